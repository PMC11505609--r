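test_that("ROUT flags gross contamination and spares clean samples", {
  set.seed(1)
  v <- c(rnorm(10), 50)
  flags <- rout_outliers(v, Q = 0.01)
  expect_true(flags[11])
  expect_equal(rout_outliers(rep(3.2, 5)), rep(FALSE, 5))
  expect_error(rout_outliers(c(1, 2)), "at least 3")
  # false-positive calibration on clean Gaussian samples
  set.seed(2)
  fp <- replicate(400, any(rout_outliers(rnorm(12), 0.01)))
  expect_lte(mean(fp), 0.05)
})

test_that("two-way ANOVA collapses to one-way when a factor is constant", {
  set.seed(5)
  d <- data.frame(value = rnorm(24), genotype = rep(c("WT", "5xFAD"), 12),
                  age = "2M")
  two <- anova_twoway(d)
  one <- anova(lm(value ~ genotype, d))
  expect_equal(two$table$F, one$`F value`[1], tolerance = 1e-9)
  expect_equal(two$table$p, one$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("two-way ANOVA is calibrated under the null and matches car", {
  set.seed(6)
  rates <- replicate(400, {
    d <- data.frame(value = rnorm(20),
                    genotype = rep(c("WT", "5xFAD"), each = 10),
                    age = rep(c("2M", "6M"), 10))
    anova_twoway(d)$table$p < 0.05
  })
  for (k in 1:3) {
    rate <- mean(rates[k, ])
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.09)
  }
  # a pure factor-A shift leaves the interaction F near its null mean
  set.seed(7)
  f_int <- replicate(300, {
    d <- data.frame(value = rnorm(20) +
                      rep(c(0, 2), each = 10),
                    genotype = rep(c("WT", "5xFAD"), each = 10),
                    age = rep(c("2M", "6M"), 10))
    anova_twoway(d)$table$F[3]
  })
  expect_lt(abs(mean(f_int) - 1), 0.3)
  d_bad <- data.frame(value = rnorm(5),
                      genotype = c("a", "a", "a", "a", "b"),
                      age = c("x", "x", "y", "y", "x"))
  expect_error(anova_twoway(d_bad), "fewer than 2")
})

test_that("Tukey reduces to the t-test for two groups and matches stats", {
  set.seed(8)
  d <- data.frame(value = rnorm(16), genotype = rep(c("a", "b"), each = 8))
  tk <- tukey_hsd(d)
  tt <- t_tests(d$value[d$genotype == "a"], d$value[d$genotype == "b"])
  expect_equal(tk$table$q, abs(tt$t) * sqrt(2), tolerance = 1e-9)
  expect_equal(tk$table$p_adj, tt$p, tolerance = 1e-6)

  d3 <- data.frame(value = rnorm(30), genotype = rep(c("a", "b", "c"),
                                                     each = 10))
  tk3 <- tukey_hsd(d3)
  ref <- stats::TukeyHSD(aov(value ~ genotype, d3))$genotype
  expect_equal(tk3$table$p_adj, unname(ref[, "p adj"]), tolerance = 1e-9)
  expect_equal(tk3$table$diff, unname(ref[, "diff"]), tolerance = 1e-12)
  expect_true(all(tk3$table$p_adj >= tk3$table$p_raw - 1e-12))

  same <- data.frame(value = rep(rnorm(6), 2),
                     genotype = rep(c("a", "b"), each = 6))
  expect_equal(tukey_hsd(same)$table$p_adj, 1, tolerance = 1e-9)
  expect_error(tukey_hsd(data.frame(value = 1:4, genotype = "a")),
               "2 groups")
})

test_that("t statistics match the formula oracle", {
  set.seed(9)
  for (k in 1:10) {
    a <- rnorm(5 + k); b <- rnorm(7)
    res <- t_tests(a, b)
    expect_equal(res$t, oracle_pooled_t(a, b), tolerance = 1e-12)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df, unname(ref$parameter))
  }
  a <- rnorm(6)
  paired_same <- t_tests(a, a, paired = TRUE)
  expect_equal(paired_same$t, 0)
  expect_equal(paired_same$p, 1)
  degen <- t_tests(c(1, 2, 3, 4), c(2, 3, 4, 5), paired = TRUE)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
  expect_error(t_tests(1, c(1, 2)), "at least 2")
})

test_that("mixed ANOVA F statistics match the aov split-plot oracle", {
  tbl <- gen_cohort(cohort_spec(n_per_group = 4, genotype_effect = 0.08,
                                age_effect = 0.05,
                                roi_effects = c(0, 0.1, 0.2, 0, 0.05, 0, 0,
                                                0.1),
                                seed = 13))
  res <- perm_mixed_anova(tbl, n_perm = 100, seed = 1)
  av <- summary(aov(value ~ genotype * age * roi + Error(subject_id),
                    data = tbl))
  btw <- av[["Error: subject_id"]][[1]]
  wth <- av[["Error: Within"]][[1]]
  f_ref <- c(btw[1:3, "F value"], wth[1:4, "F value"])
  names(f_ref) <- c("genotype", "age", "genotype:age", "roi", "genotype:roi",
                    "age:roi", "genotype:age:roi")
  for (e in res$table$effect) {
    expect_equal(res$table$F[res$table$effect == e], unname(f_ref[e]),
                 tolerance = 1e-9)
  }
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
})

test_that("permutation p-values are invariant to shifts and relabeling", {
  tbl <- gen_cohort(cohort_spec(n_per_group = 3, genotype_effect = 0.1,
                                seed = 21))
  p1 <- perm_mixed_anova(tbl, n_perm = 200, seed = 5)$table$p
  shifted <- tbl; shifted$value <- shifted$value + 7
  expect_identical(perm_mixed_anova(shifted, n_perm = 200, seed = 5)$table$p,
                   p1)
  relabeled <- tbl
  relabeled$subject_id <- sprintf("M%s", relabeled$subject_id)  # monotone
  expect_identical(perm_mixed_anova(relabeled, n_perm = 200,
                                    seed = 5)$table$p, p1)
})

test_that("permutation ANOVA detects a strong genotype effect", {
  set.seed(31)
  hits <- replicate(60, {
    tbl <- gen_cohort(cohort_spec(n_per_group = 10,
                                  genotype_effect = 0.2,
                                  residual_sd = 0.1, subject_sd = 0.05,
                                  seed = sample.int(1e6, 1)))
    res <- perm_mixed_anova(tbl, n_perm = 200, seed = 1)
    res$table$p[res$table$effect == "genotype"] <= 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("interaction p-values are roughly uniform when the interaction is null", {
  set.seed(17)
  ps <- replicate(100, {
    tbl <- gen_cohort(cohort_spec(n_per_group = 4, genotype_effect = 0.3,
                                  roi_effects = seq(0, 0.7, length.out = 8),
                                  residual_sd = 0.1,
                                  seed = sample.int(1e6, 1)))
    res <- perm_mixed_anova(tbl, n_perm = 400, seed = 2)
    res$table$p[res$table$effect == "genotype:age:roi"]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("unbalanced or malformed cohorts are rejected", {
  tbl <- gen_cohort(cohort_spec(n_per_group = 3, seed = 2))
  expect_error(perm_mixed_anova(tbl[-1, ], n_perm = 100),
               "one value per subject")
  drop_subj <- tbl[tbl$subject_id != "S001", ]
  expect_error(perm_mixed_anova(drop_subj, n_perm = 100), "unbalanced")
  expect_error(perm_mixed_anova(tbl, n_perm = 10), "n_perm")
})

test_that("simple main effects localize the stratum carrying the effect", {
  spec <- cohort_spec(n_per_group = 10, residual_sd = 0.1, subject_sd = 0.02,
                      rois = c("sub", "WM"),
                      interaction_effects = list(genotype_roi = c(0.4, 0)),
                      seed = 41)
  tbl <- gen_cohort(spec)
  sme <- simple_main_effects(tbl, effect = "genotype", by = "roi",
                             n_perm = 400, seed = 3)
  expect_lt(sme$p[sme$stratum == "sub"], 0.05)
  expect_gt(sme$p[sme$stratum == "WM"], 0.01)

  # single-stratum input is identical to the restricted permutation ANOVA
  sub_only <- tbl[tbl$roi == "sub", ]
  direct <- perm_mixed_anova(sub_only, n_perm = 400, seed = 3)
  expect_equal(sme$F[sme$stratum == "sub"],
               direct$table$F[direct$table$effect == "genotype"],
               tolerance = 1e-12)
  expect_equal(sme$p[sme$stratum == "sub"],
               direct$table$p[direct$table$effect == "genotype"])

  # a stratum where the factor has one level is skipped with a note
  wt_only <- tbl[tbl$genotype == "WT", ]
  sme2 <- simple_main_effects(wt_only, effect = "genotype", by = "roi",
                              n_perm = 400, seed = 3)
  expect_true(all(grepl("skipped", sme2$note)))
})
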