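#' Single-channel fluorescence image with physical pixel size
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size_um physical edge length of one pixel in micrometers;
#'   the study imaged at 2.02 um/px (5x) and 0.5128 um/px (20x).
#' @param channel marker label.
#' @return object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um,
                          channel = c("other", "Abeta", "GFAP", "IBA1", "MBP",
                                      "DAPI")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !length(pixels)) {
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  stop_if_not_number(pixel_size_um, "pixel_size_um", lower = 0,
                     strict_lower = TRUE)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel),
            class = "channel_image")
}

#' Region-of-interest mask
#'
#' @param mask logical matrix congruent with the image; at least one `TRUE`.
#' @param label region name.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("custom", "subiculum", "upper_cortex",
                                     "lower_cortex", "white_matter")) {
  label <- match.arg(label)
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (!any(mask)) stop("ROI mask has no TRUE pixel", call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

.check_congruent <- function(img, roi) {
  if (!all(dim(img$pixels) == dim(roi$mask))) {
    stop("image and ROI mask shapes differ", call. = FALSE)
  }
}

#' Morphological background subtraction
#'
#' Estimates the background as the grayscale morphological opening with a
#' disk structuring element and subtracts it, clipping at zero. A flat image
#' maps to all zeros; structures smaller than the disk are preserved.
#'
#' @param img a [channel_image()].
#' @param radius_px disk radius in pixels (>= 1); default 25.
#' @return background-subtracted `channel_image`.
#' @export
subtract_background <- function(img, radius_px = 25) {
  stopifnot(inherits(img, "channel_image"))
  stop_if_not_number(radius_px, "radius_px", lower = 1)
  if (2 * radius_px + 1 > min(dim(img$pixels))) {
    stop(sprintf("radius_px = %g: structuring element exceeds the %d x %d image",
                 radius_px, nrow(img$pixels), ncol(img$pixels)),
         call. = FALSE)
  }
  brush <- EBImage::makeBrush(2 * floor(radius_px) + 1, shape = "disc")
  bg <- EBImage::opening(img$pixels, brush)
  out <- pmax(img$pixels - bg, 0)
  channel_image(matrix(out, nrow(img$pixels)), img$pixel_size_um, img$channel)
}

#' Percentile-based linear contrast enhancement
#'
#' Rescales the intensity window \[P_low, P_high\] linearly to \[0, 1\],
#' clipping values outside the window.
#'
#' @param img a [channel_image()].
#' @param low_pct,high_pct percentiles in \[0, 100\], `low_pct < high_pct`.
#' @return rescaled `channel_image`.
#' @export
enhance_contrast <- function(img, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(img, "channel_image"))
  stop_if_not_number(low_pct, "low_pct", lower = 0, upper = 100)
  stop_if_not_number(high_pct, "high_pct", lower = 0, upper = 100)
  if (low_pct >= high_pct) stop("low_pct must be < high_pct", call. = FALSE)
  p <- quantile(img$pixels, c(low_pct, high_pct) / 100, names = FALSE)
  if (p[1] == p[2]) {
    stop("degenerate percentile window: P_low == P_high", call. = FALSE)
  }
  out <- pmin(pmax((img$pixels - p[1]) / (p[2] - p[1]), 0), 1)
  channel_image(out, img$pixel_size_um, img$channel)
}

# Otsu threshold on a 256-bin histogram spanning the data range. Binning over
# the range (not a fixed [0,1] window) makes the threshold exactly
# shift-equivariant: adding a constant to all pixels shifts the threshold by
# that constant.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("constant image: Otsu has no separable classes", call. = FALSE)
  }
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(pmax(floor((x - rng[1]) / width), 0), n_bins - 1L)
  h <- as.numeric(tabulate(bin + 1L, n_bins))   # numeric: cumsums can exceed int range
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  s0 <- cumsum(h * mids)
  mu0 <- s0 / w0
  mu1 <- (s0[n_bins] - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bcv[-n_bins])            # threshold after bin k
  rng[1] + k * width                       # upper edge of bin k
}

#' Binarize an image
#'
#' `method = "otsu"` picks the threshold maximizing the between-class
#' variance of a 256-bin intensity histogram; `method = "fixed"` uses the
#' supplied threshold (the original study's script threshold is unpublished,
#' so both are exposed). Positive pixels are those strictly above the
#' threshold.
#'
#' @param img a [channel_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold required iff `method = "fixed"`.
#' @return list with `mask` (logical matrix) and `threshold_used`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"),
                     fixed_threshold = NULL) {
  stopifnot(inherits(img, "channel_image"))
  method <- match.arg(method)
  if (method == "fixed" && is.null(fixed_threshold)) {
    stop("`fixed_threshold` is required when method = \"fixed\"",
         call. = FALSE)
  }
  if (method == "otsu" && !is.null(fixed_threshold)) {
    stop("`fixed_threshold` is only meaningful with method = \"fixed\"",
         call. = FALSE)
  }
  thr <- if (method == "otsu") otsu_threshold(img$pixels) else fixed_threshold
  list(mask = img$pixels > thr, threshold_used = thr)
}

#' Positive-pixel percentage within an ROI
#'
#' @param mask logical matrix of positive pixels.
#' @param roi a [roi_mask()] congruent with `mask`.
#' @return `100 * |mask & roi| / |roi|`.
#' @export
positive_pixel_pct <- function(mask, roi) {
  stopifnot(is.logical(mask), inherits(roi, "roi_mask"))
  if (!all(dim(mask) == dim(roi$mask))) {
    stop("mask and ROI shapes differ", call. = FALSE)
  }
  100 * sum(mask & roi$mask) / sum(roi$mask)
}

#' Mean raw intensity within an ROI
#'
#' Computed on the unenhanced intensities (the myelin readout is a mean
#' grayscale value, so no contrast stretch is applied first).
#'
#' @param img a [channel_image()].
#' @param roi a [roi_mask()].
#' @return arithmetic mean over ROI pixels.
#' @export
mean_intensity <- function(img, roi) {
  stopifnot(inherits(img, "channel_image"), inherits(roi, "roi_mask"))
  .check_congruent(img, roi)
  mean(img$pixels[roi$mask])
}

#' 8-connected component labeling
#'
#' EBImage's `bwlabel` is 4-connected; diagonal-touching labels are merged
#' into single objects via components of the label-adjacency graph.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask))
  nr <- nrow(lab); nc <- ncol(lab)
  if (max(lab) == 0L) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    g <- igraph::make_graph(edges = as.vector(t(pairs)), n = max(lab),
                            directed = FALSE)
    comp <- igraph::components(g)$membership
    lab[lab > 0L] <- comp[lab[lab > 0L]]
    # compact label ids
    ids <- sort(unique(lab[lab > 0L]))
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Count nuclei and report density per square millimeter
#'
#' Pipeline: background subtraction, percentile contrast enhancement, Otsu
#' binarization, 8-connected component labeling, then an area filter and a
#' centroid-in-ROI rule for objects at the ROI edge. Density divides the
#' count by the ROI area in mm^2 derived from the pixel size.
#'
#' @param img a [channel_image()] (typically the DAPI channel).
#' @param roi a [roi_mask()].
#' @param min_area_px discard components smaller than this (default 20 px).
#' @param max_area_px discard components larger than this; default
#'   `10 * median(component areas)` (rejects merged clumps).
#' @param background_radius_px disk radius for [subtract_background()].
#' @param enhance do contrast enhancement before thresholding.
#' @return list with `n_objects`, `cell_density_per_mm2`, `threshold_used`,
#'   `centroids` (n x 2, row/col), `areas_px`.
#' @export
count_nuclei <- function(img, roi, min_area_px = 20L, max_area_px = NULL,
                         background_radius_px = 25, enhance = TRUE) {
  stopifnot(inherits(img, "channel_image"), inherits(roi, "roi_mask"))
  .check_congruent(img, roi)
  min_area_px <- stop_if_not_count(min_area_px, "min_area_px", min = 1L)
  work <- subtract_background(img, background_radius_px)
  if (enhance) work <- enhance_contrast(work, 0, 100)
  bz <- binarize(work, "otsu")
  lab <- label_components(bz$mask)
  roi_area_mm2 <- sum(roi$mask) * img$pixel_size_um^2 * 1e-6
  if (max(lab) == 0L) {
    return(list(n_objects = 0L, cell_density_per_mm2 = 0,
                threshold_used = bz$threshold_used,
                centroids = matrix(numeric(0), 0, 2), areas_px = integer(0)))
  }
  fg <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  areas <- tabulate(labs)
  cent <- cbind(rowsum(fg[, 1], labs), rowsum(fg[, 2], labs)) / areas
  if (is.null(max_area_px)) max_area_px <- 10 * median(areas)
  inside <- roi$mask[cbind(pmin(pmax(round(cent[, 1]), 1), nrow(roi$mask)),
                           pmin(pmax(round(cent[, 2]), 1), ncol(roi$mask)))]
  keep <- areas >= min_area_px & areas <= max_area_px & inside
  list(n_objects = sum(keep),
       cell_density_per_mm2 = sum(keep) / roi_area_mm2,
       threshold_used = bz$threshold_used,
       centroids = cent[keep, , drop = FALSE],
       areas_px = areas[keep])
}

#' Quantify one marker channel within one ROI
#'
#' Runs the marker-appropriate readout: positive-pixel percentage after
#' background subtraction / enhancement / Otsu for plaque and glial markers,
#' mean raw grayscale for myelin, nuclei density for DAPI. All three readouts
#' are always reported; `positive_pct` uses the thresholded mask.
#'
#' @param img a [channel_image()].
#' @param roi a [roi_mask()].
#' @param background_radius_px,min_area_px passed to the sub-steps.
#' @param method,fixed_threshold binarization of the marker signal: Otsu on
#'   the contrast-enhanced image (default), or a fixed threshold applied to
#'   the background-subtracted image. Otsu assumes a bimodal histogram and
#'   will split pure noise on marker-free images, so a threshold calibrated
#'   on control images is preferable when whole groups may lack signal.
#' @return one-row data.frame: `channel`, `roi`, `positive_pct`, `mean_gray`,
#'   `n_objects`, `cell_density_per_mm2`, `threshold_used`.
#' @export
quantify_channel <- function(img, roi, background_radius_px = 25,
                             min_area_px = 20L, method = c("otsu", "fixed"),
                             fixed_threshold = NULL) {
  stopifnot(inherits(img, "channel_image"), inherits(roi, "roi_mask"))
  method <- match.arg(method)
  .check_congruent(img, roi)
  work <- subtract_background(img, background_radius_px)
  if (method == "otsu") work <- enhance_contrast(work, 0, 100)
  bz <- binarize(work, method, fixed_threshold)
  counts <- count_nuclei(img, roi, min_area_px = min_area_px,
                         background_radius_px = background_radius_px)
  data.frame(channel = img$channel, roi = roi$label,
             positive_pct = positive_pixel_pct(bz$mask, roi),
             mean_gray = mean_intensity(img, roi),
             n_objects = counts$n_objects,
             cell_density_per_mm2 = counts$cell_density_per_mm2,
             threshold_used = bz$threshold_used)
}
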