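#' Specification for a synthetic fluorescence phantom
#'
#' Describes a single-channel phantom containing plaque-like disks,
#' filamentous (glia-like) random-walk polylines, and punctate nucleus-like
#' disks at controlled densities, on the study's pixel scales (2.02 um/px at
#' 5x, 0.5128 um/px at 20x).
#'
#' @param width_px,height_px raster dimensions (default 1024 x 1024; the
#'   study does not state camera geometry).
#' @param pixel_size_um physical pixel size; default 0.5128 (20x).
#' @param plaque_count,plaque_radius_px plaque-like disks.
#' @param filament_count filament polylines.
#' @param nucleus_count,nucleus_radius_px nucleus-like disks; non-overlapping
#'   by default so the counting ground truth is unambiguous.
#' @param background_level,foreground_level intensities in \[0, 1\],
#'   `foreground_level > background_level`.
#' @param noise_sd additive Gaussian noise SD (clipped to \[0, 1\]).
#' @param allow_touching let nuclei overlap (exercises the counter's failure
#'   mode).
#' @param channel marker label for the rendered image.
#' @param seed RNG seed.
#' @return object of class `image_phantom_spec`.
#' @export
image_phantom_spec <- function(width_px = 1024L, height_px = 1024L,
                               pixel_size_um = 0.5128,
                               plaque_count = 0L, plaque_radius_px = 12,
                               filament_count = 0L,
                               nucleus_count = 0L, nucleus_radius_px = 4,
                               background_level = 0.05,
                               foreground_level = 0.8,
                               noise_sd = 0.01, allow_touching = FALSE,
                               channel = "other", seed = 1L) {
  width_px <- stop_if_not_count(width_px, "width_px", min = 8L)
  height_px <- stop_if_not_count(height_px, "height_px", min = 8L)
  stop_if_not_number(pixel_size_um, "pixel_size_um", lower = 0,
                     strict_lower = TRUE)
  plaque_count <- stop_if_not_count(plaque_count, "plaque_count")
  filament_count <- stop_if_not_count(filament_count, "filament_count")
  nucleus_count <- stop_if_not_count(nucleus_count, "nucleus_count")
  stop_if_not_number(plaque_radius_px, "plaque_radius_px", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_number(nucleus_radius_px, "nucleus_radius_px", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_number(background_level, "background_level", lower = 0,
                     upper = 1)
  stop_if_not_number(foreground_level, "foreground_level", lower = 0,
                     upper = 1)
  if (foreground_level <= background_level) {
    stop("foreground_level must exceed background_level", call. = FALSE)
  }
  stop_if_not_number(noise_sd, "noise_sd", lower = 0)
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size_um = pixel_size_um,
                 plaque_count = plaque_count,
                 plaque_radius_px = plaque_radius_px,
                 filament_count = filament_count,
                 nucleus_count = nucleus_count,
                 nucleus_radius_px = nucleus_radius_px,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 noise_sd = noise_sd, allow_touching = isTRUE(allow_touching),
                 channel = channel, seed = as.integer(seed)),
            class = "image_phantom_spec")
}

# Disk rasterization: pixel (r, c) is inside iff its center lies within the
# disk. The brute-force pixel-scan oracle in the tests uses this same
# geometric rule, computed independently.
.disk_mask <- function(nr, nc, center, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# Rejection-sample `count` disk centers with pairwise center distance
# > 2 * radius + 1 (non-touching under 8-connectivity) and margin from edges.
.place_disks <- function(count, nr, nc, radius, min_sep, max_retries = 1000L,
                         what = "nucleus_count") {
  centers <- matrix(numeric(0), 0, 2)
  margin <- radius + 1
  for (k in seq_len(count)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (!nrow(centers) ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > min_sep) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place %d non-overlapping objects after ",
                          "%d retries; reduce `%s` or the object radius"),
                   count, max_retries, what), call. = FALSE)
    }
  }
  centers
}

# Random-walk polyline of width 1-2 px; returns its pixel mask.
.filament_mask <- function(nr, nc, n_steps = 120L, wide = FALSE) {
  pos <- c(runif(1, 2, nr - 1), runif(1, 2, nc - 1))
  ang <- runif(1, 0, 2 * pi)
  m <- matrix(FALSE, nr, nc)
  for (s in seq_len(n_steps)) {
    ang <- ang + rnorm(1, 0, 0.3)
    pos <- pos + c(sin(ang), cos(ang))
    r <- round(pos[1]); c <- round(pos[2])
    if (r < 1 || r > nr || c < 1 || c > nc) break
    m[r, c] <- TRUE
    if (wide && r < nr) m[r + 1, c] <- TRUE
  }
  m
}

#' Generate a fluorescence phantom with ground truth
#'
#' Renders the requested objects at `foreground_level` on a
#' `background_level` floor, adds Gaussian noise, and clips to \[0, 1\].
#' Ground truth (per-class masks, object centers and counts, and the true
#' positive-pixel count) accompanies the image and is sufficient to score
#' every IHC quantification step.
#'
#' @param spec an [image_phantom_spec()].
#' @return list with `image` (a [channel_image()]) and `truth`: `object_mask`
#'   (all foreground), per-class masks, `nucleus_centers`, `plaque_centers`,
#'   counts, and `positive_px` (foreground pixel count).
#' @export
gen_fluorescence_image <- function(spec) {
  stopifnot(inherits(spec, "image_phantom_spec"))
  nr <- spec$height_px; nc <- spec$width_px
  with_seed(spec$seed, {
    plaque_mask <- matrix(FALSE, nr, nc)
    nucleus_mask <- matrix(FALSE, nr, nc)
    filament_mask <- matrix(FALSE, nr, nc)
    plaque_centers <- matrix(numeric(0), 0, 2)
    nucleus_centers <- matrix(numeric(0), 0, 2)
    if (spec$plaque_count > 0) {
      plaque_centers <- .place_disks(spec$plaque_count, nr, nc,
                                     spec$plaque_radius_px,
                                     2 * spec$plaque_radius_px + 2,
                                     what = "plaque_count")
      for (k in seq_len(nrow(plaque_centers))) {
        plaque_mask <- plaque_mask |
          .disk_mask(nr, nc, plaque_centers[k, ], spec$plaque_radius_px)
      }
    }
    if (spec$filament_count > 0) {
      for (k in seq_len(spec$filament_count)) {
        filament_mask <- filament_mask |
          .filament_mask(nr, nc, wide = k %% 2 == 0)
      }
    }
    if (spec$nucleus_count > 0) {
      min_sep <- if (spec$allow_touching) 0 else 2 * spec$nucleus_radius_px + 2
      nucleus_centers <- .place_disks(spec$nucleus_count, nr, nc,
                                      spec$nucleus_radius_px, min_sep)
      for (k in seq_len(nrow(nucleus_centers))) {
        nucleus_mask <- nucleus_mask |
          .disk_mask(nr, nc, nucleus_centers[k, ], spec$nucleus_radius_px)
      }
    }
    object_mask <- plaque_mask | nucleus_mask | filament_mask
    img <- matrix(spec$background_level, nr, nc)
    img[object_mask] <- spec$foreground_level
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, spec$noise_sd)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = channel_image(img, spec$pixel_size_um, spec$channel),
         truth = list(object_mask = object_mask,
                      plaque_mask = plaque_mask,
                      nucleus_mask = nucleus_mask,
                      filament_mask = filament_mask,
                      plaque_centers = plaque_centers,
                      nucleus_centers = nucleus_centers,
                      n_plaques = spec$plaque_count,
                      n_nuclei = spec$nucleus_count,
                      positive_px = sum(object_mask)))
  })
}
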