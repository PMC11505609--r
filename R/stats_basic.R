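#' ROUT outlier detection (robust center + FDR)
#'
#' Follows the published robust-regression-and-outlier-removal recipe for a
#' single sample: robust center = median; robust scale (RSDR) = the 68.27th
#' percentile of the absolute residuals times `N / (N - K)` with K = 1
#' estimated parameter; each point's t-ratio = |residual| / RSDR gives a
#' two-sided p-value at N - K df; outliers are the points surviving a
#' Benjamini-Hochberg step-up at rate `Q`, with at most 30% of the sample
#' eligible (the most extreme points). An all-identical sample has zero scale
#' and yields no outliers.
#'
#' @param values numeric vector, length >= 3.
#' @param Q FDR-like detection rate, 0 < Q < 0.5; the study used Q = 1%.
#' @return logical vector flagging outliers.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  if (length(values) < 3) stop("ROUT needs at least 3 values", call. = FALSE)
  stop_if_not_number(Q, "Q", lower = 0, upper = 0.5, strict_lower = TRUE)
  n <- length(values)
  resid <- values - median(values)
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  flags <- rep(FALSE, n)
  if (rsdr <= 0) return(flags)
  p <- 2 * pt(abs(resid) / rsdr, df = n - 1, lower.tail = FALSE)
  max_out <- floor(0.3 * n)
  if (max_out < 1) return(flags)
  ord <- order(p)
  eligible <- ord[seq_len(max_out)]
  # BH step-up restricted to the eligible (most extreme) points
  thresh <- Q * seq_len(max_out) / n
  passed <- which(p[eligible] <= thresh)
  if (length(passed)) flags[eligible[seq_len(max(passed))]] <- TRUE
  flags
}

#' Two-way factorial ANOVA (type II sums of squares)
#'
#' Fits `value ~ A * B` and reports F and p per main effect and interaction
#' using type-II sums of squares. A factor with a single level is dropped,
#' collapsing to a one-way ANOVA of the other factor.
#'
#' @param data data.frame.
#' @param value,factor_a,factor_b column names.
#' @return object of class `anova_result`: data.frame of `effect`, `df1`,
#'   `df2`, `F`, `p`, with `method = "parametric"`.
#' @export
anova_twoway <- function(data, value = "value", factor_a = "genotype",
                         factor_b = "age") {
  for (col in c(value, factor_a, factor_b)) {
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  }
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  y <- data[[value]]
  if (nlevels(A) >= 2 && nlevels(B) >= 2) {
    cells <- table(A, B)
    if (any(cells < 2)) {
      bad <- which(cells < 2, arr.ind = TRUE)[1, ]
      stop(sprintf("cell %s:%s has fewer than 2 observations",
                   levels(A)[bad[1]], levels(B)[bad[2]]), call. = FALSE)
    }
    fit <- lm(y ~ A * B)
    tab <- car::Anova(fit, type = 2)
    eff <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
    df2 <- tab["Residuals", "Df"]
    res <- data.frame(effect = eff, df1 = tab$Df[1:3], df2 = df2,
                      F = tab$`F value`[1:3], p = tab$`Pr(>F)`[1:3])
  } else {
    fac <- if (nlevels(A) >= 2) A else B
    fac_name <- if (nlevels(A) >= 2) factor_a else factor_b
    if (nlevels(fac) < 2) {
      stop("both factors are constant; nothing to test", call. = FALSE)
    }
    fit <- lm(y ~ fac)
    tab <- anova(fit)
    res <- data.frame(effect = fac_name, df1 = tab$Df[1],
                      df2 = tab$Df[2], F = tab$`F value`[1],
                      p = tab$`Pr(>F)`[1])
  }
  structure(list(table = res, method = "parametric", n_perm = NA_integer_),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> method = %s%s\n", x$method,
              if (!is.na(x$n_perm)) sprintf(", n_perm = %d", x$n_perm) else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey's HSD post hoc test
#'
#' All pairwise contrasts of one factor's group means, with the studentized
#' range statistic `q = |mean_i - mean_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`
#' (Tukey-Kramer for unequal n) referred to the studentized range
#' distribution at the residual df of the one-way model.
#'
#' @param data data.frame.
#' @param value,group column names.
#' @return object of class `posthoc_result`: data.frame of contrasts with
#'   `diff`, `q`, `p_adj` and the unadjusted t-test `p_raw`.
#' @export
tukey_hsd <- function(data, value = "value", group = "genotype") {
  g <- factor(data[[group]])
  y <- data[[value]]
  k <- nlevels(g)
  if (k < 2) stop("Tukey needs at least 2 groups", call. = FALSE)
  ns <- tapply(y, g, length)
  means <- tapply(y, g, mean)
  df <- length(y) - k
  if (df < 1) stop("no residual degrees of freedom", call. = FALSE)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df
  combs <- utils::combn(levels(g), 2)
  rows <- lapply(seq_len(ncol(combs)), function(ci) {
    a <- combs[1, ci]; b <- combs[2, ci]
    d <- means[b] - means[a]
    se_q <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
    q <- abs(d) / se_q
    t_stat <- d / sqrt(mse * (1 / ns[a] + 1 / ns[b]))
    data.frame(contrast = paste(b, "-", a), diff = unname(d),
               q = unname(q),
               p_adj = ptukey(unname(q), nmeans = k, df = df,
                              lower.tail = FALSE),
               p_raw = 2 * pt(abs(unname(t_stat)), df, lower.tail = FALSE))
  })
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 df = df, mse = mse, n_groups = k),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("<posthoc_result> %d groups, df = %d\n", x$n_groups, x$df))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Student's t-tests (paired and unpaired pooled-variance)
#'
#' The unpaired form pools the two group variances (the classical Student
#' test the study names, not Welch); the paired form is the one-sample test
#' on the differences. Zero-variance differences (or two identical constant
#' groups) are reported as degenerate rather than producing an infinite
#' statistic.
#'
#' @param a,b numeric vectors; equal length required when `paired`.
#' @param paired paired test flag.
#' @return list: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
t_tests <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired test requires equal-length vectors", call. = FALSE)
    }
    d <- a - b
    sdd <- sd(d)
    n <- length(d)
    if (sdd == 0) {
      return(list(t = if (mean(d) == 0) 0 else NA_real_, df = n - 1,
                  p = if (mean(d) == 0) 1 else NA_real_,
                  mean_diff = mean(d), degenerate = mean(d) != 0))
    }
    t_stat <- mean(d) / (sdd / sqrt(n))
    df <- n - 1
  } else {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    if (sp2 == 0) {
      same <- mean(a) == mean(b)
      return(list(t = if (same) 0 else NA_real_, df = n1 + n2 - 2,
                  p = if (same) 1 else NA_real_,
                  mean_diff = mean(a) - mean(b), degenerate = !same))
    }
    t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t_stat, df = df, p = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
       mean_diff = if (paired) mean(a - b) else mean(a) - mean(b),
       degenerate = FALSE)
}
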