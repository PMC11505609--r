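#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate coef lm mad median pf pnorm pt ptukey qt quantile
#'   rbinom rlnorm rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators behave as pure functions.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Deterministic quasi-uniform directions on the unit sphere
#'
#' Golden-angle (Fibonacci) spiral point set; used for the "isotropically
#' distributed" diffusion-encoding directions of the acquisition scheme and as
#' the base set for kurtosis averaging.
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stop_if_not_count(n, "n", min = 1L)
  i <- seq_len(n) - 0.5
  golden <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / golden
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# Direction set for kurtosis averaging: a 256-point Fibonacci spiral,
# sign-expanded over the 8 axis reflections (2048 evaluation points). The
# sign closure makes the direction average exactly invariant to the
# eigenvector sign/handedness ambiguity of the tensor eigenframe (hence to
# joint rotations), while each reflected copy retains the spiral's
# quasi-uniform quadrature accuracy.
mk_direction_set <- function(n_base = 256L) {
  base <- fibonacci_sphere(n_base)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  out <- do.call(rbind, lapply(seq_len(nrow(signs)), function(k) {
    sweep(base, 2, signs[k, ], "*")
  }))
  out / sqrt(rowSums(out^2))
}

#' Uniformly distributed random 3D rotation matrix
#'
#' Drawn via a uniform unit quaternion (Shoemake's method); consumes three
#' uniform variates from the current RNG stream.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Random symmetric positive-definite diffusion tensor
#'
#' Random eigenvalues in `lambda_range` (um^2/ms) in a uniformly random
#' orientation; used to generate physiological test tensors.
#'
#' @param lambda_range diffusivity range for the three eigenvalues.
#' @return 3 x 3 SPD matrix.
#' @export
random_spd_tensor <- function(lambda_range = c(0.2, 2.0)) {
  R <- random_rotation()
  R %*% diag(runif(3, lambda_range[1], lambda_range[2])) %*% t(R)
}

is_spd <- function(m, tol = 1e-10) {
  isTRUE(all(abs(m - t(m)) < 1e-8)) &&
    all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > tol)
}
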