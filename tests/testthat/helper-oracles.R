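# Independent brute-force oracles used across the suite.

# Exhaustive pixel scan: count raster pixels whose center lies inside a disk.
oracle_disk_pixels <- function(nr, nc, center, radius) {
  count <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) {
        count <- count + 1L
      }
    }
  }
  count
}

# Direct grayscale opening (erosion then dilation) by exhaustive min/max over
# a disk structuring element; small images only.
oracle_opening <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  minmax <- function(src, f) {
    out <- matrix(NA_real_, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      rr <- r + offs$dr; cc <- c + offs$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[r, c] <- f(src[cbind(rr[ok], cc[ok])])
    }
    out
  }
  minmax(minmax(img, min), max)
}

# Exhaustive sweep over the 256 histogram bin edges, maximizing between-class
# variance computed directly from the split pixel populations.
oracle_otsu_sweep <- function(x, n_bins = 256L) {
  rng <- range(x)
  edges <- rng[1] + (rng[2] - rng[1]) * seq_len(n_bins - 1L) / n_bins
  n <- length(x)
  bcv <- vapply(edges, function(thr) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    if (!length(lo) || !length(hi)) return(-Inf)
    (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  edges[which.max(bcv)]
}

# Direct evaluation of the DKI signal equation from full tensors, written
# independently of design_d6/design_w15 (plain loops over indices).
oracle_dki_lnsignal <- function(b, n_hat, s0, D, W_full, md) {
  d_app <- 0
  for (i in 1:3) for (j in 1:3) d_app <- d_app + n_hat[i] * n_hat[j] * D[i, j]
  w_app <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    w_app <- w_app + n_hat[i] * n_hat[j] * n_hat[k] * n_hat[l] *
      W_full[i, j, k, l]
  }
  log(s0) - b * d_app + b^2 / 6 * md^2 * w_app
}

# Student pooled-variance t from first principles.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Random SPD tensor with diffusivities in a physiological range.
random_spd_tensor <- function(lambda_range = c(0.2, 2.0)) {
  R <- admodal:::random_rotation()
  lam <- runif(3, lambda_range[1], lambda_range[2])
  R %*% diag(lam) %*% t(R)
}

# Random multi-Gaussian mixture and its exact DKI tensors.
random_mixture <- function(n_comp = 2) {
  f <- runif(n_comp); f <- f / sum(f)
  tensors <- replicate(n_comp, random_spd_tensor(), simplify = FALSE)
  mixture_dki(f, tensors)
}
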