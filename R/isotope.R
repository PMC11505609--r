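#' Mass-isotopomer distribution (MID)
#'
#' A MID holds the fractional abundances f0..fn of the M+0..M+n mass
#' isotopologues of one metabolite with `n_carbons` carbon atoms.
#'
#' @param fractions numeric vector of length `n_carbons + 1`, non-negative,
#'   summing to 1 (within `1e-9` unless `normalize = TRUE`).
#' @param metabolite metabolite name.
#' @param n_carbons number of carbons; defaults to `length(fractions) - 1`.
#' @param normalize rescale `fractions` to sum to 1.
#' @return object of class `mid`.
#' @export
mid <- function(fractions, metabolite = "metabolite",
                n_carbons = length(fractions) - 1L, normalize = FALSE) {
  n_carbons <- stop_if_not_count(n_carbons, "n_carbons", min = 1L)
  if (length(fractions) != n_carbons + 1L) {
    stop("`fractions` must have length n_carbons + 1", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < -1e-12)) {
    stop("MID fractions must be finite and non-negative", call. = FALSE)
  }
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero MID", call. = FALSE)
    fractions <- fractions / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("MID fractions sum to %g, not 1", s), call. = FALSE)
  }
  structure(list(metabolite = metabolite, n_carbons = n_carbons,
                 fractions = as.numeric(fractions)),
            class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s (%d carbons)\n", x$metabolite, x$n_carbons))
  print(setNames(round(x$fractions, 4), paste0("M+", 0:x$n_carbons)))
  invisible(x)
}

#' Natural-abundance correction matrix for the carbon skeleton
#'
#' Lower-triangular column-stochastic matrix whose entry (i, j) is the
#' binomial probability that a molecule with j tracer-labeled carbons is
#' observed at mass M+i because some of its n - j unlabeled carbons carry a
#' naturally occurring 13C:
#' `C(n - j, i - j) p^(i - j) (1 - p)^(n - i)` for i >= j.
#' Multiplying a true MID by this matrix gives the expected measured MID;
#' [correct_mid()] inverts the operation.
#'
#' @param n_carbons carbon count n (>= 1).
#' @param p_natural natural 13C abundance; default 0.0107 (terrestrial).
#' @return object of class `correction_matrix` with fields `n_carbons`,
#'   `p_natural`, `matrix` ((n+1) x (n+1)).
#' @export
correction_matrix <- function(n_carbons, p_natural = 0.0107) {
  n <- stop_if_not_count(n_carbons, "n_carbons", min = 1L)
  stop_if_not_number(p_natural, "p_natural", lower = 0, upper = 0.5 - 1e-12)
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    i <- j:n
    m[i + 1L, j + 1L] <- choose(n - j, i - j) *
      p_natural^(i - j) * (1 - p_natural)^(n - i)
  }
  dimnames(m) <- list(paste0("M+", 0:n), paste0("M+", 0:n))
  structure(list(n_carbons = n, p_natural = p_natural, matrix = m),
            class = "correction_matrix")
}

#' Forward natural-abundance convolution of a true MID
#'
#' @param true_mid a [mid()] of ground-truth tracer labeling.
#' @param cm a [correction_matrix()] of matching carbon count.
#' @return a `mid` as it would be measured (before noise).
#' @export
convolve_mid <- function(true_mid, cm) {
  stopifnot(inherits(true_mid, "mid"), inherits(cm, "correction_matrix"))
  if (true_mid$n_carbons != cm$n_carbons) {
    stop("carbon counts of MID and correction matrix differ", call. = FALSE)
  }
  mid(as.numeric(cm$matrix %*% true_mid$fractions),
      metabolite = true_mid$metabolite, normalize = TRUE)
}

#' Correct a measured MID for natural 13C abundance
#'
#' Solves the non-negative least-squares problem `min ||A x - measured||` with
#' `A` the natural-abundance convolution matrix, then renormalizes `x` to sum
#' to 1. NNLS (rather than direct inversion) keeps corrected fractions
#' non-negative on noisy data.
#'
#' @param measured a [mid()] of measured fractions.
#' @param cm a [correction_matrix()]; defaults to one built for the
#'   metabolite's carbon count at `p_natural = 0.0107`.
#' @return corrected `mid`.
#' @export
correct_mid <- function(measured, cm = correction_matrix(measured$n_carbons)) {
  stopifnot(inherits(measured, "mid"), inherits(cm, "correction_matrix"))
  if (measured$n_carbons != cm$n_carbons) {
    stop("carbon counts of MID and correction matrix differ", call. = FALSE)
  }
  if (sum(measured$fractions) <= 0) {
    stop("measured MID is all zero; nothing to correct", call. = FALSE)
  }
  x <- pracma::lsqnonneg(cm$matrix, measured$fractions)$x
  if (sum(x) <= 0) stop("NNLS returned an all-zero solution", call. = FALSE)
  mid(x, metabolite = measured$metabolite, normalize = TRUE)
}

#' Molecular carbon labeling (MCL)
#'
#' The weighted average fraction of 13C-labeled carbons in a metabolite,
#' `sum(i * f_i) / n` over the corrected MID; 0 for a fully unlabeled and 1
#' for a fully labeled molecule.
#'
#' @param x a [mid()] (corrected for natural abundance).
#' @return fraction in \[0, 1\].
#' @export
mcl <- function(x) {
  stopifnot(inherits(x, "mid"))
  sum((0:x$n_carbons) * x$fractions) / x$n_carbons
}

#' M+X labeling percentage
#'
#' @param x a [mid()].
#' @param X isotopologue index, 0 <= X <= n.
#' @return `100 * f_X`.
#' @export
mx_percent <- function(x, X) {
  stopifnot(inherits(x, "mid"))
  X <- stop_if_not_count(X, "X", min = 0L)
  if (X > x$n_carbons) {
    stop(sprintf("X = %d exceeds the %d carbons of %s", X, x$n_carbons,
                 x$metabolite), call. = FALSE)
  }
  100 * x$fractions[X + 1L]
}

# Long/wide MID table -> list of mid objects keyed by row.
.row_mid <- function(row, m_cols) {
  n <- as.integer(row[["n_carbons"]])
  f <- as.numeric(row[m_cols[seq_len(n + 1L)]])
  mid(f, metabolite = row[["metabolite"]], n_carbons = n, normalize = TRUE)
}

#' Group summaries of 13C enrichment with two-group comparisons
#'
#' Applies natural-abundance correction to every row of a replicate MID
#' table, computes MCL and M+X percentages, and summarizes each
#' metabolite-by-condition panel as mean and SD per group with an unpaired
#' Student's t-test between the two genotype groups (the layout of the
#' enrichment figures: metabolite x substrate x region).
#'
#' @param tbl data.frame with columns `sample_id`, `genotype`, `region`,
#'   `substrate`, `metabolite`, `n_carbons` and `m0`, `m1`, ... measured
#'   fractional abundances.
#' @param p_natural natural 13C abundance used in the correction.
#' @param value one of `"mcl"` or `"mX"` (with `X` via `mx`); the statistic
#'   summarized and tested.
#' @param mx isotopologue index when `value = "mx"`.
#' @return data.frame with one row per metabolite x region x substrate:
#'   per-genotype mean/SD/n and `t`, `df`, `p` of the unpaired test.
#' @export
summarize_groups <- function(tbl, p_natural = 0.0107, value = c("mcl", "mx"),
                             mx = NULL) {
  value <- match.arg(value)
  need <- c("sample_id", "genotype", "region", "substrate", "metabolite",
            "n_carbons")
  if (!all(need %in% names(tbl))) {
    stop("MID table lacks columns: ",
         paste(setdiff(need, names(tbl)), collapse = ", "), call. = FALSE)
  }
  m_cols <- grep("^m[0-9]+$", names(tbl), value = TRUE)
  m_cols <- m_cols[order(as.integer(sub("^m", "", m_cols)))]
  cms <- list()
  stat <- vapply(seq_len(nrow(tbl)), function(r) {
    row <- tbl[r, , drop = FALSE]
    n <- as.integer(row$n_carbons)
    key <- as.character(n)
    if (is.null(cms[[key]])) {
      cms[[key]] <<- correction_matrix(n, p_natural)
    }
    corrected <- correct_mid(.row_mid(row, m_cols), cms[[key]])
    if (value == "mcl") mcl(corrected) else mx_percent(corrected, mx)
  }, numeric(1))
  tbl$.stat <- stat

  panels <- unique(tbl[c("metabolite", "region", "substrate")])
  out <- do.call(rbind, lapply(seq_len(nrow(panels)), function(k) {
    sel <- tbl$metabolite == panels$metabolite[k] &
      tbl$region == panels$region[k] & tbl$substrate == panels$substrate[k]
    sub <- tbl[sel, ]
    groups <- sort(unique(sub$genotype))
    if (any(table(sub$genotype) < 2)) {
      stop(sprintf("panel %s/%s/%s has a genotype group with < 2 replicates",
                   panels$metabolite[k], panels$region[k],
                   panels$substrate[k]), call. = FALSE)
    }
    g1 <- sub$.stat[sub$genotype == groups[1]]
    g2 <- sub$.stat[sub$genotype == groups[2]]
    tt <- t_tests(g1, g2, paired = FALSE)
    data.frame(panels[k, , drop = FALSE],
               group1 = groups[1], mean1 = mean(g1), sd1 = sd(g1),
               n1 = length(g1),
               group2 = groups[2], mean2 = mean(g2), sd2 = sd(g2),
               n2 = length(g2),
               t = tt$t, df = tt$df, p = tt$p, row.names = NULL)
  }))
  attr(out, "value") <- if (value == "mcl") "mcl" else paste0("m", mx)
  out
}
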