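# ---- symmetric tensor bookkeeping -----------------------------------------
# D: 6 unique elements in order (xx, yy, zz, xy, xz, yz), multiplicities
# (1,1,1,2,2,2). W: 15 unique elements of the fully symmetric rank-4 tensor,
# with multinomial multiplicities summing to 81.

.d_idx <- cbind(i = c(1, 2, 3, 1, 1, 2), j = c(1, 2, 3, 2, 3, 3))
.d_mult <- c(1, 1, 1, 2, 2, 2)

.w_table_build <- function() {
  grid <- as.matrix(expand.grid(1:3, 1:3, 1:3, 1:3))
  keys <- apply(grid, 1, function(r) paste(sort(r), collapse = ""))
  uk <- unique(keys)
  idx <- t(vapply(uk, function(k) as.integer(strsplit(k, "")[[1]]),
                  integer(4)))
  mult <- as.integer(table(keys)[uk])
  list(idx = idx, mult = mult, full_key = match(keys, uk), grid = grid)
}
.w_table <- .w_table_build()

d6_to_mat <- function(d6) {
  m <- matrix(0, 3, 3)
  m[cbind(.d_idx[, 1], .d_idx[, 2])] <- d6
  m[cbind(.d_idx[, 2], .d_idx[, 1])] <- d6
  m
}

mat_to_d6 <- function(m) m[cbind(.d_idx[, 1], .d_idx[, 2])]

w15_to_full <- function(w15) {
  array(w15[.w_table$full_key], dim = c(3, 3, 3, 3))
}

full_to_w15 <- function(full) {
  vapply(seq_len(15), function(k) {
    i <- .w_table$idx[k, ]
    full[i[1], i[2], i[3], i[4]]
  }, numeric(1))
}

# Symmetrize an arbitrary rank-4 array over all index permutations and return
# the 15-vector. Contraction with n (x) n (x) n (x) n is unchanged by this.
sym_w15 <- function(full) {
  perms <- matrix(c(1,2,3,4, 1,2,4,3, 1,3,2,4, 1,3,4,2, 1,4,2,3, 1,4,3,2,
                    2,1,3,4, 2,1,4,3, 2,3,1,4, 2,3,4,1, 2,4,1,3, 2,4,3,1,
                    3,1,2,4, 3,1,4,2, 3,2,1,4, 3,2,4,1, 3,4,1,2, 3,4,2,1,
                    4,1,2,3, 4,1,3,2, 4,2,1,3, 4,2,3,1, 4,3,1,2, 4,3,2,1),
                  ncol = 4, byrow = TRUE)
  s <- array(0, dim = c(3, 3, 3, 3))
  for (p in seq_len(nrow(perms))) {
    s <- s + aperm(full, perms[p, ])
  }
  full_to_w15(s / 24)
}

# Rotate tensors into a new frame with coordinates x' = R x.
rotate_d <- function(d_mat, R) R %*% d_mat %*% t(R)

rotate_w15 <- function(w15, R) {
  full <- w15_to_full(w15)
  m <- matrix(full, 9, 9)          # unfold (i,j) x (k,l), column-major
  RR <- R %x% R                    # (RR)[(j-1)*3+i, (b-1)*3+a] = R[i?,..]
  # column-major packing: index (i,j) -> i + 3*(j-1); need G with
  # G[i + 3*(j-1), a + 3*(b-1)] = R[i,a] * R[j,b], which is kronecker(R, R)
  # with R's kronecker convention reversed: use R %x% R on swapped order.
  G <- matrix(0, 9, 9)
  for (i in 1:3) for (j in 1:3) for (a in 1:3) for (b in 1:3) {
    G[i + 3 * (j - 1), a + 3 * (b - 1)] <- R[i, a] * R[j, b]
  }
  m2 <- G %*% m %*% t(G)
  full_to_w15(array(m2, dim = c(3, 3, 3, 3)))
}

# Design blocks: rows of n (x) n contracted with unique D / W elements
# (symmetry multiplicities applied).
design_d6 <- function(dirs) {
  cols <- lapply(seq_len(6), function(k) {
    .d_mult[k] * dirs[, .d_idx[k, 1]] * dirs[, .d_idx[k, 2]]
  })
  do.call(cbind, cols)
}

design_w15 <- function(dirs) {
  cols <- lapply(seq_len(15), function(k) {
    i <- .w_table$idx[k, ]
    .w_table$mult[k] * dirs[, i[1]] * dirs[, i[2]] * dirs[, i[3]] * dirs[, i[4]]
  })
  do.call(cbind, cols)
}

# ---- gradient scheme -------------------------------------------------------

#' Diffusion gradient scheme
#'
#' @param b_values non-negative b-values in ms/um^2, one per measurement.
#' @param directions matrix of encoding directions (unit vectors for b > 0;
#'   rows match `b_values`).
#' @return object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(b_values, directions) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3 || nrow(directions) != length(b_values)) {
    stop("`directions` must be an n x 3 matrix matching `b_values`",
         call. = FALSE)
  }
  if (any(b_values < 0) || any(!is.finite(b_values))) {
    stop("b-values must be finite and non-negative", call. = FALSE)
  }
  dwi <- b_values > 0
  if (!any(!dwi)) stop("scheme needs at least one b = 0 measurement",
                       call. = FALSE)
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms[dwi] - 1) > 1e-9)) {
    stop("b > 0 directions must be unit vectors (within 1e-9)", call. = FALSE)
  }
  structure(list(b_values = as.numeric(b_values), directions = directions),
            class = "gradient_scheme")
}

#' The study's acquisition scheme
#'
#' Five b = 0 images plus 30 isotropically distributed directions at each of
#' the four shells b = 0.4, 0.8, 1.5, 2.0 ms/um^2 (125 measurements).
#'
#' @param n_dirs directions per shell.
#' @param shells shell b-values in ms/um^2.
#' @param n_b0 number of unweighted measurements.
#' @return a [gradient_scheme()].
#' @export
study_scheme <- function(n_dirs = 30L, shells = c(0.4, 0.8, 1.5, 2.0),
                         n_b0 = 5L) {
  dirs30 <- fibonacci_sphere(n_dirs)
  b <- c(rep(0, n_b0), rep(shells, each = n_dirs))
  dirs <- rbind(matrix(0, n_b0, 3),
                do.call(rbind, rep(list(dirs30), length(shells))))
  gradient_scheme(b, dirs)
}

#' Read an FSL-style bval/bvec pair as a gradient scheme
#'
#' @param bval_path,bvec_path text files: one row of b-values; three rows of
#'   direction components.
#' @param units `"ms/um2"` (used throughout the package) or `"s/mm2"`
#'   (divided by 1000 on read).
#' @return a [gradient_scheme()].
#' @export
read_scheme <- function(bval_path, bvec_path, units = c("ms/um2", "s/mm2")) {
  units <- match.arg(units)
  b <- scan(bval_path, quiet = TRUE)
  if (units == "s/mm2") b <- b / 1000
  v <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  gradient_scheme(b, t(v))
}

#' Write a gradient scheme as FSL-style bval/bvec files
#'
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output paths.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$b_values, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$directions), 1, paste, collapse = " "),
             bvec_path)
  invisible(NULL)
}

# ---- signal model ----------------------------------------------------------

#' Rician noise-floor adjustment
#'
#' Method-of-moments removal of the positive bias of magnitude MRI signals:
#' `adjusted = sqrt(max(S^2 - k * sigma^2, 0))` with `k = 1`
#' (`method = "moment1"`, the default) or `k = 2` (`method = "moment2"`,
#' motivated by `E[magnitude^2] = S^2 + 2 sigma^2`). The literature uses both
#' conventions, so the factor is a config option rather than a guess.
#'
#' @param signal non-negative signal vector.
#' @param sigma noise SD (>= 0).
#' @param method `"moment1"` or `"moment2"`.
#' @return adjusted signal vector.
#' @export
rician_floor_adjust <- function(signal, sigma,
                                method = c("moment1", "moment2")) {
  method <- match.arg(method)
  stop_if_not_number(sigma, "sigma", lower = 0)
  if (any(signal < 0)) stop("magnitude signals must be >= 0", call. = FALSE)
  k <- if (method == "moment1") 1 else 2
  sqrt(pmax(signal^2 - k * sigma^2, 0))
}

#' DKI design matrix
#'
#' Maps the 22-parameter vector `(ln S0, D_6, Wh_15)` to log-signal, where
#' `Wh = MD^2 * W` is the kurtosis tensor pre-multiplied by the squared mean
#' diffusivity (the standard substitution that makes the signal equation
#' linear in the parameters). Row for measurement (b, n):
#' `ln S = ln S0 - b * sum n_i n_j D_ij + (b^2/6) * sum n_i n_j n_k n_l Wh_ijkl`
#' with symmetry multiplicities folded into the unique-element columns; b = 0
#' rows carry only the intercept.
#'
#' @param scheme a [gradient_scheme()].
#' @return 125 x 22 (in general n x 22) design matrix.
#' @export
build_design <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b <- scheme$b_values
  dirs <- scheme$directions
  dirs[b == 0, ] <- 0
  X <- cbind(1, -b * design_d6(dirs), (b^2 / 6) * design_w15(dirs))
  if (qr(X)$rank < 22) {
    stop("scheme yields fewer than 22 independent rows; DKI fit is under-determined",
         call. = FALSE)
  }
  colnames(X) <- c("lnS0", paste0("D", apply(.d_idx, 1, paste, collapse = "")),
                   paste0("W", apply(.w_table$idx, 1, paste, collapse = "")))
  X
}

#' Predict DKI signals from tensors
#'
#' Direct evaluation of the DKI signal equation (no design matrix), used as
#' the independent forward model for simulation and in tests as the oracle
#' against `build_design`.
#'
#' @param scheme a [gradient_scheme()].
#' @param s0 unweighted signal.
#' @param D 3 x 3 symmetric diffusion tensor (um^2/ms).
#' @param W 15-vector (or full array) kurtosis tensor, dimensionless.
#' @return signal vector.
#' @export
predict_dki_signal <- function(scheme, s0, D, W) {
  if (is.array(W) && length(dim(W)) == 4) W <- full_to_w15(W)
  md <- sum(diag(D)) / 3
  b <- scheme$b_values
  dirs <- scheme$directions
  dirs[b == 0, ] <- 0
  d_app <- as.numeric(design_d6(dirs) %*% mat_to_d6(D))
  w_app <- as.numeric(design_w15(dirs) %*% W)
  s0 * exp(-b * d_app + (b^2 / 6) * md^2 * w_app)
}

# ---- voxel fit -------------------------------------------------------------

#' Fit the DKI signal equation in one voxel
#'
#' Weighted linear least squares on log-signal (weights = squared predicted
#' signal, the first-order variance correction for the log transform)
#' initializes the 22 parameters; Levenberg-Marquardt nonlinear least squares
#' on the exponentiated model refines them. The apparent kurtosis on the fit
#' directions can be kept inside `k_bounds` by a soft penalty, and a
#' non-positive-definite initial D is projected to the nearest SPD matrix.
#'
#' @param signals measured signal vector (after any floor adjustment);
#'   non-positive entries are masked out of the fit.
#' @param scheme a [gradient_scheme()].
#' @param k_bounds allowed apparent-kurtosis range on the fit directions
#'   (default `c(0, 10)`); `NULL` disables the penalty.
#' @param penalty_weight weight of the kurtosis penalty residuals.
#' @param refine run the nonlinear refinement (default TRUE).
#' @return object of class `dki_fit`: `s0`, `D` (3 x 3), `W` (15-vector),
#'   `converged`, `flagged`, `n_used`.
#' @export
fit_dki_voxel <- function(signals, scheme, k_bounds = c(0, 10),
                          penalty_weight = 0.1, refine = TRUE) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(signals) != length(scheme$b_values)) {
    stop("signal vector does not match the scheme", call. = FALSE)
  }
  keep <- is.finite(signals) & signals > 0
  if (all(!keep)) {
    return(structure(list(s0 = NA_real_, D = matrix(NA_real_, 3, 3),
                          W = rep(NA_real_, 15), converged = FALSE,
                          flagged = TRUE, n_used = 0L, skipped = TRUE),
                     class = "dki_fit"))
  }
  X_all <- build_design(scheme)
  X <- X_all[keep, , drop = FALSE]
  y <- log(signals[keep])
  if (qr(X)$rank < 22) {
    stop("fewer than 22 usable measurements; DKI fit is under-determined",
         call. = FALSE)
  }
  beta <- qr.coef(qr(X), y)
  w <- exp(X %*% beta)^2                       # squared predicted signal
  beta <- lm.wfit(X, y, as.numeric(w))$coefficients

  # SPD projection of the linear initializer if needed
  Dm <- d6_to_mat(beta[2:7])
  ev <- eigen(Dm, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    lam <- pmax(ev$values, 1e-6)
    Dm <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    beta[2:7] <- mat_to_d6(Dm)
  }

  converged <- TRUE
  if (refine) {
    s_obs <- signals[keep]
    pen_dirs <- scheme$directions[scheme$b_values > 0, , drop = FALSE]
    pen_d6 <- design_d6(pen_dirs)
    pen_w15 <- design_w15(pen_dirs)
    resid_fn <- function(p) {
      r <- s_obs - exp(as.numeric(X %*% p))
      if (!is.null(k_bounds)) {
        d_app <- as.numeric(pen_d6 %*% p[2:7])
        wh_app <- as.numeric(pen_w15 %*% p[8:22])
        k_app <- wh_app / pmax(d_app, 1e-8)^2    # Wh = MD^2 W => K directly
        r <- c(r, penalty_weight * pmax(k_bounds[1] - k_app, 0),
               penalty_weight * pmax(k_app - k_bounds[2], 0))
      }
      r
    }
    nl <- tryCatch(
      minpack.lm::nls.lm(par = beta, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(nl) || nl$info %in% c(0, 5, 9)) {
      converged <- FALSE                         # keep linear estimate
    } else {
      beta <- coef(nl)
    }
  }

  Dm <- d6_to_mat(beta[2:7])
  md <- sum(diag(Dm)) / 3
  W <- if (md > 0) beta[8:22] / md^2 else rep(NA_real_, 15)
  structure(list(s0 = exp(beta[[1]]), D = Dm, W = as.numeric(W),
                 converged = converged, flagged = !converged,
                 n_used = sum(keep), skipped = FALSE),
            class = "dki_fit")
}

# ---- scalar metrics --------------------------------------------------------

#' MD, FA and MK from a DKI fit
#'
#' MD = tr(D)/3; FA from the eigenvalues of D; MK is the average apparent
#' kurtosis `K(n) = (MD^2 / D(n)^2) * W(n)` over a direction set: by default
#' a 256-point spherical spiral symmetrized over the 8 axis reflections and
#' evaluated in the eigenframe of D, which makes MK exactly invariant under
#' joint rotation of the tensors. Pass the acquisition directions via
#' `mk_directions` to average over the measured directions instead.
#'
#' @param fit a `dki_fit`, or a list with elements `D` (3 x 3) and `W`
#'   (15-vector), e.g. ground truth tensors.
#' @param mk_directions optional n x 3 unit-vector set; when supplied, the
#'   average is taken over these directions in the laboratory frame.
#' @return list with `MD` (um^2/ms), `FA` in \[0, 1\], `MK`.
#' @export
dki_metrics <- function(fit, mk_directions = NULL) {
  D <- fit$D
  if (is.null(D) || any(!is.finite(D))) {
    return(list(MD = NA_real_, FA = NA_real_, MK = NA_real_))
  }
  if (all(abs(D) < 1e-15)) stop("zero diffusion tensor", call. = FALSE)
  W <- fit$W
  if (is.array(W) && length(dim(W)) == 4) W <- full_to_w15(W)
  ev <- eigen(D, symmetric = TRUE)
  lam <- ev$values
  md <- mean(lam)
  fa <- sqrt(3 / 2) * sqrt(sum((lam - md)^2)) / sqrt(sum(lam^2))
  mk <- NA_real_
  if (!is.null(W) && all(is.finite(W))) {
    if (is.null(mk_directions)) {
      dirs <- mk_direction_set()
      w_frame <- rotate_w15(W, t(ev$vectors))   # tensor in eigenframe
      d_app <- as.numeric(dirs^2 %*% lam)
      w_app <- as.numeric(design_w15(dirs) %*% w_frame)
    } else {
      dirs <- mk_directions
      d_app <- as.numeric(design_d6(dirs) %*% mat_to_d6(D))
      w_app <- as.numeric(design_w15(dirs) %*% W)
    }
    mk <- mean(md^2 / d_app^2 * w_app)
  }
  list(MD = md, FA = fa, MK = mk)
}

# ---- volume fitting and ROI summaries -------------------------------------

#' Fit DKI over a masked 4D volume
#'
#' @param volume 4D array (x, y, z, measurement).
#' @param scheme a [gradient_scheme()].
#' @param mask optional 3D logical array of voxels to fit (default: voxels
#'   with positive mean b0).
#' @param sigma Rician noise SD for [rician_floor_adjust()] (0 = skip).
#' @param floor_method passed to [rician_floor_adjust()].
#' @param refine run the nonlinear refinement per voxel.
#' @param preprocessed logical flag recorded in the output: whether the input
#'   volumes were already denoised/Gibbs-corrected upstream.
#' @return list of 3D maps `MD`, `FA`, `MK`, `S0`, logical `flagged`, and the
#'   fit `mask`.
#' @export
fit_dki_volume <- function(volume, scheme, mask = NULL, sigma = 0,
                           floor_method = "moment1", refine = TRUE,
                           preprocessed = TRUE) {
  dims <- dim(volume)
  stopifnot(length(dims) == 4)
  b0 <- apply(volume[, , , scheme$b_values == 0, drop = FALSE], 1:3, mean)
  if (is.null(mask)) mask <- b0 > 0
  maps <- list(MD = array(NA_real_, dims[1:3]), FA = array(NA_real_, dims[1:3]),
               MK = array(NA_real_, dims[1:3]), S0 = array(NA_real_, dims[1:3]),
               flagged = array(FALSE, dims[1:3]))
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    s <- volume[idx[v, 1], idx[v, 2], idx[v, 3], ]
    if (sigma > 0) s <- rician_floor_adjust(s, sigma, floor_method)
    fit <- fit_dki_voxel(s, scheme, refine = refine)
    if (isTRUE(fit$skipped)) next
    m <- dki_metrics(fit)
    maps$MD[idx[v, , drop = FALSE]] <- m$MD
    maps$FA[idx[v, , drop = FALSE]] <- m$FA
    maps$MK[idx[v, , drop = FALSE]] <- m$MK
    maps$S0[idx[v, , drop = FALSE]] <- fit$s0
    maps$flagged[idx[v, , drop = FALSE]] <- fit$flagged
  }
  maps$mask <- mask
  maps$preprocessed <- isTRUE(preprocessed)
  maps
}

#' ROI summaries of metric maps with whole-brain-normalized volume
#'
#' Hemispheres (or any sub-masks sharing a label) are pooled by passing them
#' as one mask. Relative volume is the pooled ROI voxel count over the
#' whole-brain voxel count (voxel volume cancels for same-grid masks but is
#' reported).
#'
#' @param maps named list of 3D metric arrays (e.g. `MD`, `FA`, `MK`).
#' @param roi_masks named list of 3D logical arrays.
#' @param brain_mask 3D logical array; the normalization denominator.
#' @param voxel_size_mm length-3 voxel edge lengths.
#' @return data.frame: one row per ROI with per-metric means, `n_voxels`,
#'   `volume_mm3`, `relative_volume`.
#' @export
summarize_rois <- function(maps, roi_masks, brain_mask,
                           voxel_size_mm = c(0.15, 0.15, 0.2)) {
  if (!length(roi_masks) || is.null(names(roi_masks))) {
    stop("`roi_masks` must be a named list", call. = FALSE)
  }
  vox_vol <- prod(voxel_size_mm)
  n_brain <- sum(brain_mask)
  if (n_brain == 0) stop("empty whole-brain mask", call. = FALSE)
  do.call(rbind, lapply(names(roi_masks), function(lbl) {
    m <- roi_masks[[lbl]]
    if (!all(dim(m) == dim(brain_mask))) {
      stop(sprintf("ROI '%s' shape differs from the brain mask", lbl),
           call. = FALSE)
    }
    if (!any(m)) stop(sprintf("ROI '%s' is empty", lbl), call. = FALSE)
    means <- lapply(maps, function(map) mean(map[m], na.rm = TRUE))
    data.frame(roi = lbl, as.data.frame(setNames(means, names(maps))),
               n_voxels = sum(m), volume_mm3 = sum(m) * vox_vol,
               relative_volume = sum(m) / n_brain)
  }))
}
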