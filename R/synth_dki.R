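#' Exact DKI tensors of a multi-Gaussian mixture
#'
#' For a mixture of Gaussian compartments with fractions `f_c` and tensors
#' `D_c`, the cumulant expansion of the signal gives
#' `D = sum f_c D_c` and `MD^2 W_ijkl = 3 * sym(sum f_c D_c (x) D_c - D (x) D)`,
#' i.e. the directional apparent kurtosis is
#' `K(n) = 3 Var_c(n' D_c n) / (n' D n)^2`. For two isotropic compartments
#' with diffusivities d1, d2 at f = 1/2 this reduces to the closed form
#' `MK = 3 (d1 - d2)^2 / (d1 + d2)^2`.
#'
#' @param fractions signal fractions summing to 1.
#' @param tensors list of 3 x 3 SPD matrices (um^2/ms).
#' @return list with `D` (3 x 3), `W` (15-vector) and the scalar metrics of
#'   the mixture.
#' @export
mixture_dki <- function(fractions, tensors) {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    stop("signal fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (length(fractions) != length(tensors)) {
    stop("`fractions` and `tensors` lengths differ", call. = FALSE)
  }
  for (tn in tensors) {
    if (!is_spd(tn)) stop("compartment tensor is not symmetric positive-definite",
                          call. = FALSE)
  }
  D <- Reduce(`+`, Map(function(f, tn) f * tn, fractions, tensors))
  md <- sum(diag(D)) / 3
  second <- Reduce(`+`, Map(function(f, tn) {
    f * array(outer(as.vector(tn), as.vector(tn)), dim = c(3, 3, 3, 3))
  }, fractions, tensors))
  outerD <- array(outer(as.vector(D), as.vector(D)), dim = c(3, 3, 3, 3))
  W <- 3 / md^2 * sym_w15(second - outerD)
  c(list(D = D, W = W), dki_metrics(list(D = D, W = W)))
}

#' Specification for a synthetic DKI phantom
#'
#' A small 3D volume partitioned into slabs along the first axis, one region
#' per entry of `regions`, each a multi-Gaussian compartment mixture whose
#' exact DKI ground truth is known analytically.
#'
#' @param shape length-3 voxel grid dimensions.
#' @param voxel_size_mm length-3 voxel edge lengths (default the study's
#'   0.15 x 0.15 mm in-plane and 0.2 mm slices).
#' @param regions named list; each element a list with `fractions` (summing
#'   to 1) and `tensors` (list of SPD 3 x 3 matrices).
#' @param scheme a [gradient_scheme()], default [study_scheme()].
#' @param s0 unweighted signal level.
#' @param snr signal-to-noise ratio at s0 (`Inf` = noiseless); Rician noise
#'   is applied as the magnitude of the signal plus complex Gaussian noise
#'   with per-channel SD `s0 / snr`.
#' @param seed RNG seed.
#' @return object of class `dki_phantom_spec`.
#' @export
dki_phantom_spec <- function(shape = c(6L, 4L, 2L),
                             voxel_size_mm = c(0.15, 0.15, 0.2),
                             regions = list(
                               wm = list(fractions = 1,
                                         tensors = list(diag(c(1.4, 0.3, 0.3)))),
                               gm = list(fractions = c(0.5, 0.5),
                                         tensors = list(diag(0.5, 3),
                                                        diag(1.5, 3)))),
                             scheme = study_scheme(), s0 = 1,
                             snr = Inf, seed = 1L) {
  if (length(shape) != 3 || any(shape < 1)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive reals", call. = FALSE)
  }
  if (shape[1] < length(regions)) {
    stop("first axis shorter than the number of regions", call. = FALSE)
  }
  stopifnot(inherits(scheme, "gradient_scheme"))
  stop_if_not_number(s0, "s0", lower = 0, strict_lower = TRUE)
  if (!identical(snr, Inf)) stop_if_not_number(snr, "snr", lower = 0,
                                               strict_lower = TRUE)
  truth <- lapply(regions, function(r) mixture_dki(r$fractions, r$tensors))
  structure(list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 regions = regions, truth = truth, scheme = scheme, s0 = s0,
                 snr = snr, seed = as.integer(seed)),
            class = "dki_phantom_spec")
}

#' Generate a 4D DKI phantom with ground truth maps
#'
#' Noiseless signal per voxel is the compartment sum
#' `sum_c f_c * s0 * exp(-b * n' D_c n)`; Rician noise (magnitude of signal
#' plus complex Gaussian, SD = `s0 / snr` per channel) is applied when `snr`
#' is finite. Ground-truth MD/FA/MK maps come from the analytic mixture
#' cumulants, so they are exact for the multi-Gaussian signal at b -> 0.
#'
#' @param spec a [dki_phantom_spec()].
#' @return list: `volume` (4D array), `region_masks` (named list of 3D
#'   logicals), `brain_mask`, ground-truth `MD`/`FA`/`MK` maps, `truth`
#'   (per-region tensors and metrics), `sigma` (noise SD used), `scheme`.
#' @export
gen_dki_volume <- function(spec) {
  stopifnot(inherits(spec, "dki_phantom_spec"))
  dims <- spec$shape
  n_meas <- length(spec$scheme$b_values)
  b <- spec$scheme$b_values
  dirs <- spec$scheme$directions
  dirs[b == 0, ] <- 0
  n_reg <- length(spec$regions)
  # slab boundaries along the first axis
  cuts <- round(seq(0, dims[1], length.out = n_reg + 1))
  region_id <- array(0L, dims)
  for (k in seq_len(n_reg)) {
    region_id[(cuts[k] + 1):cuts[k + 1], , ] <- k
  }
  region_signal <- lapply(spec$regions, function(r) {
    sig <- rep(0, n_meas)
    for (c_i in seq_along(r$fractions)) {
      d_app <- rowSums((dirs %*% r$tensors[[c_i]]) * dirs)
      sig <- sig + r$fractions[c_i] * spec$s0 * exp(-b * d_app)
    }
    sig
  })
  volume <- array(0, c(dims, n_meas))
  md_map <- array(NA_real_, dims)
  fa_map <- array(NA_real_, dims)
  mk_map <- array(NA_real_, dims)
  flat <- as.vector(region_id)
  vol_mat <- matrix(0, prod(dims), n_meas)
  for (k in seq_len(n_reg)) {
    vol_mat[flat == k, ] <- matrix(region_signal[[k]], sum(flat == k),
                                   n_meas, byrow = TRUE)
    md_map[region_id == k] <- spec$truth[[k]]$MD
    fa_map[region_id == k] <- spec$truth[[k]]$FA
    mk_map[region_id == k] <- spec$truth[[k]]$MK
  }
  sigma <- 0
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    vol_mat <- with_seed(spec$seed, {
      re <- vol_mat + matrix(rnorm(length(vol_mat), 0, sigma), nrow(vol_mat))
      im <- matrix(rnorm(length(vol_mat), 0, sigma), nrow(vol_mat))
      sqrt(re^2 + im^2)
    })
  }
  volume <- array(vol_mat, c(dims, n_meas))
  region_masks <- setNames(lapply(seq_len(n_reg), function(k) region_id == k),
                           names(spec$regions))
  list(volume = volume, region_masks = region_masks,
       brain_mask = region_id > 0, MD = md_map, FA = fa_map, MK = mk_map,
       truth = spec$truth, sigma = sigma, scheme = spec$scheme)
}

#' Write a DKI phantom to NIfTI + bval/bvec files
#'
#' @param phantom output of [gen_dki_volume()].
#' @param dir output directory.
#' @param prefix file name stem.
#' @return invisibly, the paths written.
#' @export
write_dki_phantom <- function(phantom, dir, prefix = "dwi") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dwi_path <- file.path(dir, paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$volume), dwi_path)
  mask_path <- file.path(dir, paste0(prefix, "_rois.nii.gz"))
  lab <- array(0L, dim(phantom$brain_mask))
  for (k in seq_along(phantom$region_masks)) {
    lab[phantom$region_masks[[k]]] <- k
  }
  RNifti::writeNifti(RNifti::asNifti(lab), mask_path)
  bval <- file.path(dir, paste0(prefix, ".bval"))
  bvec <- file.path(dir, paste0(prefix, ".bvec"))
  write_scheme(phantom$scheme, bval, bvec)
  invisible(c(dwi = dwi_path, rois = mask_path, bval = bval, bvec = bvec))
}
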