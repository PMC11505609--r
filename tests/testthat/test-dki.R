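test_that("gradient schemes validate and the study scheme has 125 rows", {
  sch <- study_scheme()
  expect_length(sch$b_values, 125)
  expect_equal(sum(sch$b_values == 0), 5)
  expect_equal(sort(unique(sch$b_values)), c(0, 0.4, 0.8, 1.5, 2.0))
  norms <- sqrt(rowSums(sch$directions[sch$b_values > 0, ]^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_error(gradient_scheme(c(1, 2), rbind(c(1, 0, 0), c(1, 0, 0))),
               "b = 0")
  expect_error(gradient_scheme(c(0, 1), rbind(c(0, 0, 0), c(2, 0, 0))),
               "unit")
})

test_that("scheme files round-trip through bval/bvec", {
  sch <- study_scheme()
  dir <- withr::local_tempdir()
  write_scheme(sch, file.path(dir, "x.bval"), file.path(dir, "x.bvec"))
  back <- read_scheme(file.path(dir, "x.bval"), file.path(dir, "x.bvec"))
  expect_equal(back$b_values, sch$b_values, tolerance = 1e-6)
  expect_equal(back$directions, sch$directions, tolerance = 1e-6,
               ignore_attr = TRUE)
  # s/mm^2 auto-scaling
  writeLines(paste(sch$b_values * 1000, collapse = " "),
             file.path(dir, "y.bval"))
  back2 <- read_scheme(file.path(dir, "y.bval"), file.path(dir, "x.bvec"),
                       units = "s/mm2")
  expect_equal(back2$b_values, sch$b_values, tolerance = 1e-6)
})

test_that("Rician floor adjustment follows the moment formulas", {
  s <- c(0, 0.5, 1, 2)
  expect_equal(rician_floor_adjust(s, 0), s)
  expect_equal(rician_floor_adjust(0.3, 0.3), 0)
  expect_equal(rician_floor_adjust(1, 0.2), sqrt(1 - 0.04))
  expect_equal(rician_floor_adjust(1, 0.2, "moment2"), sqrt(1 - 0.08))
  # Monte-Carlo: with the 2 sigma^2 subtraction, E[adjusted^2] ~ S^2 at SNR 5
  set.seed(20)
  S <- 1; sig <- 0.2
  mag <- sqrt((S + rnorm(1e5, 0, sig))^2 + rnorm(1e5, 0, sig)^2)
  adj <- rician_floor_adjust(mag, sig, "moment2")
  expect_lt(abs(mean(adj^2) - S^2) / S^2, 0.02)
})

test_that("design matrix reproduces the signal equation", {
  sch <- study_scheme()
  X <- build_design(sch)
  expect_equal(dim(X), c(125, 22))
  b0_rows <- X[sch$b_values == 0, ]
  expect_true(all(b0_rows[, 1] == 1))
  expect_true(all(b0_rows[, -1] == 0))

  # axis-aligned single direction
  one <- gradient_scheme(c(0, 1.5), rbind(c(0, 0, 0), c(1, 0, 0)))
  X1 <- build_design_unchecked <- tryCatch(build_design(one),
                                           error = function(e) e)
  expect_s3_class(X1, "error")   # 2 rows cannot determine 22 parameters
  row <- cbind(1, -1.5 * admodal:::design_d6(rbind(c(1, 0, 0))),
               (1.5^2 / 6) * admodal:::design_w15(rbind(c(1, 0, 0))))
  expect_equal(row[1, 2], -1.5)               # D_xx regressor
  expect_equal(row[1, 8], 1.5^2 / 6)          # Wh_xxxx regressor
  expect_true(all(row[1, c(3:7, 9:22)] == 0))

  # predicted ln-signal from design x parameters vs direct evaluation
  set.seed(15)
  D <- random_spd_tensor()
  mx <- random_mixture()
  md <- mean(eigen(mx$D, symmetric = TRUE)$values)
  W_full <- admodal:::w15_to_full(mx$W)
  bs <- runif(200, 0.1, 2)
  dirs <- fibonacci_sphere(200)
  sch2 <- gradient_scheme(c(0, bs), rbind(c(0, 0, 0), dirs))
  X2 <- build_design(sch2)
  theta <- c(log(2), admodal:::mat_to_d6(mx$D), md^2 * mx$W)
  pred <- as.numeric(X2 %*% theta)
  direct <- vapply(seq_len(200), function(i) {
    oracle_dki_lnsignal(bs[i], dirs[i, ], 2, mx$D, W_full, md)
  }, numeric(1))
  expect_equal(pred[-1], direct, tolerance = 1e-12)
})

test_that("noiseless fits recover Gaussian and DKI-class parameters", {
  sch <- study_scheme()
  # isotropic Gaussian: MD = d, FA = 0, MK = 0
  s <- predict_dki_signal(sch, 50, diag(0.9, 3), rep(0, 15))
  m <- dki_metrics(fit_dki_voxel(s, sch))
  expect_equal(m$MD, 0.9, tolerance = 1e-6)
  expect_equal(m$FA, 0, tolerance = 1e-6)
  expect_equal(m$MK, 0, tolerance = 1e-6)

  set.seed(21)
  for (k in 1:10) {
    mx <- random_mixture(2)
    s_k <- predict_dki_signal(sch, 1, mx$D, mx$W)
    fit <- fit_dki_voxel(s_k, sch)
    m_k <- dki_metrics(fit)
    expect_equal(m_k$MD, mx$MD, tolerance = 1e-6)
    expect_equal(m_k$FA, mx$FA, tolerance = 1e-6)
    expect_equal(m_k$MK, mx$MK, tolerance = 1e-5)
    rel_resid <- max(abs(predict_dki_signal(sch, fit$s0, fit$D,
                                            fit$W) - s_k) / s_k)
    expect_lt(rel_resid, 1e-8)
  }
})

test_that("fitted kurtosis approaches the mixture closed form as b shrinks", {
  d1 <- 0.5; d2 <- 2.0
  k_true <- 3 * (d1 - d2)^2 / (d1 + d2)^2
  fitted_k <- function(scale) {
    sch <- study_scheme(shells = c(0.4, 0.8, 1.5, 2.0) * scale)
    b <- sch$b_values
    s <- 0.5 * exp(-b * d1) + 0.5 * exp(-b * d2)
    dki_metrics(fit_dki_voxel(s, sch))$MK
  }
  k_full <- fitted_k(1)     # the study's b-range: truncation biases MK low
  k_small <- fitted_k(0.25)
  expect_lt(abs(k_small - k_true) / k_true, 0.05)
  expect_lt(abs(k_full - k_true) / k_true, 0.35)
  expect_lt(k_full, k_small)   # bias grows with b_max
})

test_that("metrics are exactly rotation-equivariant", {
  set.seed(33)
  mx <- random_mixture(2)
  m0 <- dki_metrics(list(D = mx$D, W = mx$W))
  for (k in 1:10) {
    R <- admodal:::random_rotation()
    m1 <- dki_metrics(list(D = admodal:::rotate_d(mx$D, R),
                           W = admodal:::rotate_w15(mx$W, R)))
    expect_equal(m1$MD, m0$MD, tolerance = 1e-9)
    expect_equal(m1$FA, m0$FA, tolerance = 1e-9)
    expect_equal(m1$MK, m0$MK, tolerance = 1e-9)
  }
})

test_that("256-direction MK agrees with a dense spherical average", {
  set.seed(7)
  done <- 0
  while (done < 5) {
    mx <- random_mixture(2)
    if (mx$MK < 0.05) next     # relative comparison needs non-trivial MK
    done <- done + 1
    m <- dki_metrics(list(D = mx$D, W = mx$W))
    dirs <- fibonacci_sphere(10000)
    d_app <- as.numeric(admodal:::design_d6(dirs) %*%
                          admodal:::mat_to_d6(mx$D))
    w_app <- as.numeric(admodal:::design_w15(dirs) %*% mx$W)
    mk_dense <- mean(m$MD^2 / d_app^2 * w_app)
    expect_lt(abs(m$MK - mk_dense) / abs(mk_dense), 0.005)
  }
})

test_that("metrics handle limit cases", {
  expect_equal(dki_metrics(list(D = diag(1, 3), W = rep(0, 15)))$FA, 0)
  near_linear <- dki_metrics(list(D = diag(c(2, 1e-6, 1e-6)),
                                  W = rep(0, 15)))
  expect_gt(near_linear$FA, 0.999)
  expect_error(dki_metrics(list(D = matrix(0, 3, 3), W = rep(0, 15))),
               "zero")
})

test_that("noisy voxel fits meet the SNR-50 error budget", {
  sch <- study_scheme()
  mx <- mixture_dki(c(0.5, 0.5), list(diag(0.5, 3), diag(1.5, 3)))
  s <- predict_dki_signal(sch, 1, mx$D, mx$W)
  sig <- 1 / 50
  set.seed(44)
  errs <- t(replicate(150, {
    mag <- sqrt((s + rnorm(length(s), 0, sig))^2 +
                  rnorm(length(s), 0, sig)^2)
    m <- dki_metrics(fit_dki_voxel(rician_floor_adjust(mag, sig), sch))
    c(md = abs(m$MD - mx$MD) / mx$MD, mk = abs(m$MK - mx$MK) / mx$MK)
  }))
  expect_lt(median(errs[, "md"]), 0.02)
  expect_lt(median(errs[, "mk"]), 0.10)
})

test_that("volume fitting and ROI summaries recover the phantom truth", {
  spec <- dki_phantom_spec(shape = c(4, 2, 2), snr = Inf)
  ph <- gen_dki_volume(spec)
  maps <- fit_dki_volume(ph$volume, ph$scheme, mask = ph$brain_mask)
  summ <- summarize_rois(maps[c("MD", "FA", "MK")], ph$region_masks,
                         ph$brain_mask, spec$voxel_size_mm)
  expect_equal(sum(summ$relative_volume), 1, tolerance = 1e-12)
  # wm region is a single Gaussian (inside the model class): exact recovery;
  # gm region is a true biexponential: the fit carries the truncation bias
  wm <- summ[summ$roi == "wm", ]
  expect_equal(wm$MD, ph$truth$wm$MD, tolerance = 1e-6)
  expect_equal(wm$FA, ph$truth$wm$FA, tolerance = 1e-6)
  expect_equal(wm$MK, ph$truth$wm$MK, tolerance = 1e-5)
  gm <- summ[summ$roi == "gm", ]
  expect_equal(gm$MD, ph$truth$gm$MD, tolerance = 0.03)
  expect_lt(abs(gm$FA - ph$truth$gm$FA), 1e-3)
  expect_equal(gm$MK, ph$truth$gm$MK, tolerance = 0.35)
  # ROI == whole brain: relative volume 1; constant map mean
  whole <- summarize_rois(list(MD = array(2.5, dim(ph$brain_mask))),
                          list(all = ph$brain_mask), ph$brain_mask)
  expect_equal(whole$relative_volume, 1)
  expect_equal(whole$MD, 2.5)
  expect_error(summarize_rois(maps["MD"],
                              list(bad = array(FALSE, dim(ph$brain_mask))),
                              ph$brain_mask), "empty")
})

test_that("phantoms round-trip through NIfTI and bval/bvec files", {
  spec <- dki_phantom_spec(shape = c(4, 2, 1), snr = 30, seed = 3)
  ph <- gen_dki_volume(spec)
  dir <- withr::local_tempdir()
  paths <- write_dki_phantom(ph, dir)
  vol <- RNifti::readNifti(paths["dwi"])
  expect_equal(dim(vol), dim(ph$volume))
  expect_equal(as.array(vol), ph$volume, tolerance = 1e-6,
               ignore_attr = TRUE)
  sch <- read_scheme(paths["bval"], paths["bvec"])
  expect_equal(sch$b_values, ph$scheme$b_values, tolerance = 1e-6)
})
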