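#' Specification for a synthetic subject cohort
#'
#' Additive linear mixed model over the study's factor structure: genotype
#' (WT vs 5xFAD) and age (2M vs 6M) between subjects, ROI within subject,
#' with a subject random intercept:
#' `y = mu + genotype + age + roi + interactions + subject + residual`.
#' Effects are mean shifts applied to the second factor level (5xFAD, 6M)
#' and per-ROI.
#'
#' @param n_per_group subjects per genotype x age cell (>= 2; default 7,
#'   matching the study's 6-7 animals per genotype and age).
#' @param rois ROI labels (default the study's eight pooled regions).
#' @param grand_mean baseline response.
#' @param genotype_effect shift added for 5xFAD subjects.
#' @param age_effect shift added at 6M.
#' @param roi_effects per-ROI shifts (recycled to `length(rois)`).
#' @param interaction_effects named list with optional entries
#'   `genotype_age` (scalar), `genotype_roi`, `age_roi`, `genotype_age_roi`
#'   (per-ROI vectors); omitted entries are 0.
#' @param residual_sd,subject_sd residual and random-intercept SDs
#'   (`residual_sd > 0`, `subject_sd >= 0`).
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 7L,
                        rois = c("sub", "CA", "hip", "CC", "WM", "LC", "UC",
                                 "neo"),
                        grand_mean = 1, genotype_effect = 0, age_effect = 0,
                        roi_effects = 0, interaction_effects = list(),
                        residual_sd = 0.1, subject_sd = 0.05, seed = 1L) {
  n_per_group <- stop_if_not_count(n_per_group, "n_per_group", min = 2L)
  stop_if_not_number(residual_sd, "residual_sd", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_number(subject_sd, "subject_sd", lower = 0)
  R <- length(rois)
  if (R < 1) stop("need at least one ROI", call. = FALSE)
  roi_effects <- rep_len(roi_effects, R)
  ie <- list(genotype_age = 0, genotype_roi = rep(0, R),
             age_roi = rep(0, R), genotype_age_roi = rep(0, R))
  for (nm in names(interaction_effects)) {
    if (!nm %in% names(ie)) stop("unknown interaction effect: ", nm,
                                 call. = FALSE)
    ie[[nm]] <- if (nm == "genotype_age") {
      stop_if_not_number(interaction_effects[[nm]], nm)
    } else rep_len(interaction_effects[[nm]], R)
  }
  structure(list(n_per_group = n_per_group, rois = rois,
                 grand_mean = grand_mean, genotype_effect = genotype_effect,
                 age_effect = age_effect, roi_effects = roi_effects,
                 interaction_effects = ie, residual_sd = residual_sd,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a long-format cohort table with known effects
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `subject_id`, `genotype` (WT/5xFAD),
#'   `age` (2M/6M), `roi`, `value`; the generating spec is attached as
#'   `attr(, "truth")`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  genotypes <- c("WT", "5xFAD")
  ages <- c("2M", "6M")
  R <- length(spec$rois)
  with_seed(spec$seed, {
    rows <- list()
    subj_counter <- 0L
    for (gt in genotypes) for (ag in ages) {
      for (s in seq_len(spec$n_per_group)) {
        subj_counter <- subj_counter + 1L
        u <- rnorm(1, 0, spec$subject_sd)
        is_tg <- gt == "5xFAD"
        is_old <- ag == "6M"
        mu <- spec$grand_mean +
          is_tg * spec$genotype_effect +
          is_old * spec$age_effect +
          spec$roi_effects +
          (is_tg && is_old) * spec$interaction_effects$genotype_age +
          is_tg * spec$interaction_effects$genotype_roi +
          is_old * spec$interaction_effects$age_roi +
          (is_tg && is_old) * spec$interaction_effects$genotype_age_roi
        val <- mu + u + rnorm(R, 0, spec$residual_sd)
        rows[[subj_counter]] <- data.frame(
          subject_id = sprintf("S%03d", subj_counter),
          genotype = gt, age = ag, roi = spec$rois, value = val)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- spec
    out
  })
}
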