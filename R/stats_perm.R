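# ---- balanced split-plot (mixed) ANOVA decomposition ----------------------
# Two between-subject factors (genotype, age) and one within-subject factor
# (ROI). Between effects are tested against the subject-within-cell stratum,
# within effects against the subject-by-ROI residual stratum. Requires equal
# subject counts per between cell; factors with a single level are dropped.

# g, a: integer vectors (level ids) of length N; Y: N x R matrix.
# between_part / within_part skip strata not needed (permutation speed).
.mixed_core <- function(Y, g, a, m_s = rowMeans(Y), between_part = TRUE,
                        within_part = TRUE) {
  N <- nrow(Y); R <- ncol(Y)
  G <- max(g); A <- max(a)
  cell <- (g - 1L) * A + a
  n_cell <- tabulate(cell, G * A)
  mu <- mean(m_s)

  out <- list()
  # between stratum (on subject means; SS scaled by R)
  mg <- rowsum(m_s, g)[, 1] / tabulate(g, G)
  ma <- rowsum(m_s, a)[, 1] / tabulate(a, A)
  mcell <- rowsum(m_s, cell)[, 1] / n_cell
  ss_subj <- R * sum((m_s - mcell[cell])^2)
  df_subj <- N - G * A
  ms_subj <- ss_subj / df_subj
  if (between_part && G > 1) {
    ss <- R * sum(tabulate(g, G) * (mg - mu)^2)
    out$genotype <- c(ss = ss, df1 = G - 1, df2 = df_subj,
                      F = (ss / (G - 1)) / ms_subj)
  }
  if (between_part && A > 1) {
    ss <- R * sum(tabulate(a, A) * (ma - mu)^2)
    out$age <- c(ss = ss, df1 = A - 1, df2 = df_subj,
                 F = (ss / (A - 1)) / ms_subj)
  }
  if (between_part && G > 1 && A > 1) {
    gi <- ((seq_len(G * A) - 1L) %/% A) + 1L
    ai <- ((seq_len(G * A) - 1L) %% A) + 1L
    dev <- mcell - mg[gi] - ma[ai] + mu
    ss <- R * sum(n_cell * dev^2)
    out$`genotype:age` <- c(ss = ss, df1 = (G - 1) * (A - 1), df2 = df_subj,
                            F = (ss / ((G - 1) * (A - 1))) / ms_subj)
  }

  if (within_part && R > 1) {
    colm <- colMeans(Y)
    ss_r <- N * sum((colm - mu)^2)
    Mg <- rowsum(Y, g) / tabulate(g, G)
    Ma <- rowsum(Y, a) / tabulate(a, A)
    Mcell <- rowsum(Y, cell) / n_cell
    dev_gr <- sweep(sweep(Mg, 1, mg), 2, colm) + mu
    ss_gr <- (N / G) * sum(dev_gr^2)
    dev_ar <- sweep(sweep(Ma, 1, ma), 2, colm) + mu
    ss_ar <- (N / A) * sum(dev_ar^2)
    gi <- ((seq_len(G * A) - 1L) %/% A) + 1L
    ai <- ((seq_len(G * A) - 1L) %% A) + 1L
    dev3 <- Mcell - Mg[gi, , drop = FALSE] - Ma[ai, , drop = FALSE] -
      mcell + outer(mg[gi] + ma[ai] - mu, rep(1, R)) +
      outer(rep(1, G * A), colm)
    ss_gar <- (N / (G * A)) * sum(dev3^2)
    ss_wtot <- sum((Y - m_s)^2)
    ss_err <- ss_wtot - ss_r - (if (G > 1) ss_gr else 0) -
      (if (A > 1) ss_ar else 0) -
      (if (G > 1 && A > 1) ss_gar else 0)
    df_err <- (N - G * A) * (R - 1)
    ms_err <- ss_err / df_err
    out$roi <- c(ss = ss_r, df1 = R - 1, df2 = df_err,
                 F = (ss_r / (R - 1)) / ms_err)
    if (G > 1) {
      df1 <- (G - 1) * (R - 1)
      out$`genotype:roi` <- c(ss = ss_gr, df1 = df1, df2 = df_err,
                              F = (ss_gr / df1) / ms_err)
    }
    if (A > 1) {
      df1 <- (A - 1) * (R - 1)
      out$`age:roi` <- c(ss = ss_ar, df1 = df1, df2 = df_err,
                         F = (ss_ar / df1) / ms_err)
    }
    if (G > 1 && A > 1) {
      df1 <- (G - 1) * (A - 1) * (R - 1)
      out$`genotype:age:roi` <- c(ss = ss_gar, df1 = df1, df2 = df_err,
                                  F = (ss_gar / df1) / ms_err)
    }
  }
  out
}

.between_effects <- c("genotype", "age", "genotype:age")

# Reshape a long cohort table to (Y, g, a) with balance checks.
.cohort_matrix <- function(data, value, subject, between, within) {
  for (col in c(value, subject, between, within)) {
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  }
  subj <- factor(as.character(data[[subject]]))
  roi <- factor(as.character(data[[within]]))
  N <- nlevels(subj); R <- nlevels(roi)
  if (nrow(data) != N * R ||
      any(table(subj, roi) != 1)) {
    stop("cohort table must hold exactly one value per subject x ROI",
         call. = FALSE)
  }
  Y <- matrix(NA_real_, N, R,
              dimnames = list(levels(subj), levels(roi)))
  Y[cbind(as.integer(subj), as.integer(roi))] <- data[[value]]
  lab <- function(col) {
    v <- tapply(as.character(data[[col]]), subj, function(x) {
      u <- unique(x)
      if (length(u) != 1) stop("subject spans multiple levels of ", col,
                               call. = FALSE)
      u
    })
    factor(v[levels(subj)])
  }
  g <- lab(between[1])
  a <- if (length(between) >= 2) lab(between[2]) else factor(rep("all", N))
  cells <- table(g, a)
  if (any(cells == 0)) stop("empty genotype x age cell", call. = FALSE)
  if (length(unique(as.vector(cells))) != 1) {
    stop("unbalanced design: unequal subject counts per between-subject cell",
         call. = FALSE)
  }
  list(Y = Y, g = as.integer(g), a = as.integer(a),
       g_levels = levels(g), a_levels = levels(a))
}

#' Permutational mixed-design ANOVA
#'
#' Three-way mixed ANOVA (two between-subject factors, one within-subject
#' factor) with permutation p-values. Observed F statistics come from the
#' balanced split-plot decomposition (between effects against the
#' subject-within-cell stratum, within effects against the residual stratum).
#' Null distributions respect each effect's exchangeability stratum: whole
#' subjects are shuffled across between-group labels for between effects, and
#' ROI labels are shuffled within each subject for within effects. The
#' p-value is the plain proportion of permuted F values strictly larger than
#' the observed F (`p_correction = "add_one"` switches to the
#' (b + 1)/(m + 1) estimator).
#'
#' @param data long-format cohort table.
#' @param value,subject,within column names; `between` gives one or two
#'   between-subject factor columns.
#' @param n_perm number of permutations (>= 100; the study used 10,000).
#' @param seed RNG seed for the permutation stream.
#' @param p_correction `"proportion"` (as defined above) or `"add_one"`.
#' @return `anova_result` whose table has per-effect `F`, `df1`, `df2`,
#'   permutation `p`, and the parametric `p_param` from the F distribution.
#' @export
perm_mixed_anova <- function(data, value = "value", subject = "subject_id",
                             between = c("genotype", "age"), within = "roi",
                             n_perm = 10000L, seed = 1L,
                             p_correction = c("proportion", "add_one")) {
  p_correction <- match.arg(p_correction)
  n_perm <- stop_if_not_count(n_perm, "n_perm", min = 100L)
  cm <- .cohort_matrix(data, value, subject, between, within)
  Y <- cm$Y; g <- cm$g; a <- cm$a
  N <- nrow(Y); R <- ncol(Y)
  obs <- .mixed_core(Y, g, a)
  effects <- names(obs)
  exceed <- setNames(numeric(length(effects)), effects)
  has_between <- any(effects %in% .between_effects)
  has_within <- R > 1

  with_seed(seed, {
    m_s <- rowMeans(Y)
    for (p_i in seq_len(n_perm)) {
      if (has_between) {
        pi_b <- sample.int(N)
        fb <- .mixed_core(Y, g[pi_b], a[pi_b], m_s = m_s,
                          within_part = FALSE)
        for (e in intersect(effects, .between_effects)) {
          if (fb[[e]]["F"] > obs[[e]]["F"]) exceed[e] <- exceed[e] + 1
        }
      }
      if (has_within) {
        idx <- t(vapply(seq_len(N), function(s) sample.int(R), integer(R)))
        Yp <- matrix(Y[cbind(rep(seq_len(N), R),
                             as.vector(idx))], N, R)
        fw <- .mixed_core(Yp, g, a, m_s = m_s, between_part = FALSE)
        for (e in setdiff(effects, .between_effects)) {
          if (fw[[e]]["F"] > obs[[e]]["F"]) exceed[e] <- exceed[e] + 1
        }
      }
    }
  })

  p_perm <- if (p_correction == "proportion") {
    exceed / n_perm
  } else {
    (exceed + 1) / (n_perm + 1)
  }
  tab <- do.call(rbind, lapply(effects, function(e) {
    v <- obs[[e]]
    data.frame(effect = e, df1 = unname(v["df1"]), df2 = unname(v["df2"]),
               F = unname(v["F"]), p = unname(p_perm[e]),
               p_param = pf(unname(v["F"]), v["df1"], v["df2"],
                            lower.tail = FALSE))
  }))
  warn <- character(0)
  if (n_perm < 1 / 0.05) {
    warn <- "n_perm too small to resolve alpha = 0.05"
  }
  structure(list(table = tab, method = "permutation",
                 n_perm = as.integer(n_perm), warnings = warn,
                 n_subjects = N, n_rois = R),
            class = "anova_result")
}

#' Simple main effects by permutation
#'
#' Tests one factor within each level of another (the follow-up the study
#' applies to significant interactions): the table is restricted to each
#' stratum of `by` and the permutation ANOVA is re-run on the restriction,
#' which collapses factors that become constant. A stratum in which `effect`
#' has a single level is reported as skipped.
#'
#' @param data long-format cohort table (see [perm_mixed_anova()]).
#' @param effect factor whose effect is tested (column name).
#' @param by stratifying factor (column name), e.g. the ROI.
#' @inheritParams perm_mixed_anova
#' @return data.frame with one row per stratum: `stratum`, `effect`, `F`,
#'   `df1`, `df2`, `p`, `note`.
#' @export
simple_main_effects <- function(data, effect = "age", by = "roi",
                                value = "value", subject = "subject_id",
                                between = c("genotype", "age"),
                                within = "roi", n_perm = 1000L, seed = 1L) {
  strata <- unique(as.character(data[[by]]))
  out <- lapply(strata, function(s) {
    sub <- data[as.character(data[[by]]) == s, , drop = FALSE]
    if (length(unique(sub[[effect]])) < 2) {
      return(data.frame(stratum = s, effect = effect, F = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                        note = "skipped: single level"))
    }
    res <- perm_mixed_anova(sub, value = value, subject = subject,
                            between = between, within = within,
                            n_perm = n_perm, seed = seed)
    row <- res$table[res$table$effect == effect, , drop = FALSE]
    if (!nrow(row)) {
      return(data.frame(stratum = s, effect = effect, F = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                        note = "skipped: effect absent after collapse"))
    }
    data.frame(stratum = s, effect = effect, F = row$F, df1 = row$df1,
               df2 = row$df2, p = row$p, note = "")
  })
  do.call(rbind, out)
}
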