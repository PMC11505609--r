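#' Default ground-truth labeling table for a tracer substrate
#'
#' A parameterized toy TCA-cycle labeling pattern for the three substrates
#' used in the slice incubations (2.5 mM uniformly 13C-labeled glucose, 5 mM
#' \[1,2-13C\]acetate, 1.0 mM uniformly labeled glutamine). Glucose feeds
#' pyruvate (M+3 lactate/alanine) and acetyl-CoA (M+2 entry into the TCA
#' cycle); \[1,2-13C\]acetate labels acetyl-CoA M+2 directly (the astrocytic
#' route); glutamine labels glutamate M+5 and, after one cycle turn, M+4/M+2
#' species. The numbers are plausible first-turn enrichments, not a flux fit.
#'
#' @param substrate one of `"U13C_glucose"`, `"12C13_acetate"`,
#'   `"U13C_glutamine"`.
#' @return named list of [mid()] objects (ground truth before natural
#'   abundance).
#' @export
default_true_mids <- function(substrate = c("U13C_glucose", "12C13_acetate",
                                            "U13C_glutamine")) {
  substrate <- match.arg(substrate)
  mk <- function(name, f) mid(f, metabolite = name, normalize = TRUE)
  switch(substrate,
    U13C_glucose = list(
      lactate   = mk("lactate",   c(0.55, 0.03, 0.04, 0.38)),
      alanine   = mk("alanine",   c(0.62, 0.03, 0.03, 0.32)),
      citrate   = mk("citrate",   c(0.60, 0.04, 0.22, 0.05, 0.07, 0.01, 0.01)),
      akg       = mk("akg",       c(0.64, 0.04, 0.20, 0.05, 0.06, 0.01)),
      succinate = mk("succinate", c(0.68, 0.05, 0.20, 0.04, 0.03)),
      malate    = mk("malate",    c(0.66, 0.05, 0.21, 0.05, 0.03)),
      glutamate = mk("glutamate", c(0.62, 0.05, 0.21, 0.05, 0.06, 0.01)),
      glutamine = mk("glutamine", c(0.70, 0.04, 0.16, 0.04, 0.05, 0.01)),
      gaba      = mk("gaba",      c(0.72, 0.04, 0.17, 0.04, 0.03)),
      aspartate = mk("aspartate", c(0.67, 0.05, 0.20, 0.05, 0.03))),
    `12C13_acetate` = list(
      citrate   = mk("citrate",   c(0.72, 0.02, 0.18, 0.02, 0.05, 0.005, 0.005)),
      akg       = mk("akg",       c(0.75, 0.02, 0.16, 0.02, 0.05)),
      succinate = mk("succinate", c(0.78, 0.02, 0.15, 0.02, 0.03)),
      malate    = mk("malate",    c(0.77, 0.02, 0.16, 0.02, 0.03)),
      glutamate = mk("glutamate", c(0.74, 0.02, 0.17, 0.02, 0.05)),
      glutamine = mk("glutamine", c(0.70, 0.02, 0.21, 0.02, 0.05)),
      gaba      = mk("gaba",      c(0.78, 0.02, 0.16, 0.02, 0.02)),
      aspartate = mk("aspartate", c(0.77, 0.02, 0.16, 0.02, 0.03))),
    U13C_glutamine = list(
      glutamine = mk("glutamine", c(0.30, 0.02, 0.03, 0.03, 0.07, 0.55)),
      glutamate = mk("glutamate", c(0.42, 0.03, 0.05, 0.04, 0.08, 0.38)),
      akg       = mk("akg",       c(0.50, 0.03, 0.06, 0.05, 0.08, 0.28)),
      succinate = mk("succinate", c(0.55, 0.04, 0.08, 0.06, 0.27)),
      malate    = mk("malate",    c(0.57, 0.04, 0.09, 0.06, 0.24)),
      citrate   = mk("citrate",   c(0.55, 0.04, 0.08, 0.05, 0.22, 0.04, 0.02)),
      gaba      = mk("gaba",      c(0.60, 0.04, 0.09, 0.06, 0.21)),
      aspartate = mk("aspartate", c(0.58, 0.04, 0.09, 0.06, 0.23))))
}

#' Specification for synthetic GC-MS isotopologue measurements
#'
#' @param substrate tracer substrate label (see [default_true_mids()]).
#' @param true_mids named list of [mid()] ground-truth labeling patterns;
#'   defaults to the substrate's toy TCA table.
#' @param p_natural natural 13C abundance convolved into the measurements.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (MS abundances are positive with roughly proportional
#'   noise).
#' @param n_replicates biological replicates to simulate (>= 1).
#' @param seed RNG seed; the generator is a pure function of its arguments,
#'   seed included.
#' @return object of class `tracer_spec`.
#' @export
tracer_spec <- function(substrate = "U13C_glucose",
                        true_mids = default_true_mids(substrate),
                        p_natural = 0.0107, noise_cv = 0.02,
                        n_replicates = 4L, seed = 1L) {
  stop_if_not_number(p_natural, "p_natural", lower = 0, upper = 0.5 - 1e-12)
  stop_if_not_number(noise_cv, "noise_cv", lower = 0)
  n_replicates <- stop_if_not_count(n_replicates, "n_replicates", min = 1L)
  if (!length(true_mids) || is.null(names(true_mids))) {
    stop("`true_mids` must be a named list of mid objects", call. = FALSE)
  }
  for (m in true_mids) {
    stopifnot(inherits(m, "mid"))
    if (abs(sum(m$fractions) - 1) > 1e-12) {
      stop("each true MID must sum to 1 within 1e-12", call. = FALSE)
    }
  }
  structure(list(substrate = substrate, true_mids = true_mids,
                 p_natural = p_natural, noise_cv = noise_cv,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "tracer_spec")
}

#' Generate a replicate table of measured MIDs
#'
#' Each measured MID is the natural-abundance convolution of the ground-truth
#' MID (see [correction_matrix()]) with multiplicative lognormal noise of the
#' requested CV applied per isotopologue channel, renormalized to sum 1.
#'
#' @param spec a [tracer_spec()].
#' @param genotype,region labels copied into the output table.
#' @return data.frame in the wide layout [summarize_groups()] reads
#'   (`sample_id`, `genotype`, `region`, `substrate`, `metabolite`,
#'   `n_carbons`, `m0..m6`), with the ground-truth spec attached as
#'   `attr(, "truth")`.
#' @export
gen_mids <- function(spec, genotype = "WT", region = "cortex") {
  stopifnot(inherits(spec, "tracer_spec"))
  max_n <- max(vapply(spec$true_mids, function(m) m$n_carbons, integer(1)))
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  with_seed(spec$seed, {
    rows <- list()
    for (rep_i in seq_len(spec$n_replicates)) {
      for (met in names(spec$true_mids)) {
        tm <- spec$true_mids[[met]]
        cm <- correction_matrix(tm$n_carbons, spec$p_natural)
        f <- as.numeric(cm$matrix %*% tm$fractions)
        if (spec$noise_cv > 0) {
          f <- f * rlnorm(length(f), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }
        f <- f / sum(f)
        row <- c(list(sample_id = sprintf("%s_%s_r%02d", genotype, region,
                                          rep_i),
                      genotype = genotype, region = region,
                      substrate = spec$substrate, metabolite = met,
                      n_carbons = tm$n_carbons),
                 setNames(as.list(c(f, rep(NA_real_, max_n - tm$n_carbons))),
                          paste0("m", 0:max_n)))
        rows[[length(rows) + 1L]] <- as.data.frame(row)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- spec
    out
  })
}

#' Shift labeling toward M+0 to emulate hypometabolism
#'
#' Utility for building group contrasts: moves a fraction of every labeled
#' isotopologue's mass into M+0, scaling MCL by `1 - reduction`.
#'
#' @param true_mids named list of [mid()] objects.
#' @param reduction fraction in \[0, 1\] of labeling removed.
#' @return named list of adjusted `mid` objects.
#' @export
scale_labeling <- function(true_mids, reduction) {
  stop_if_not_number(reduction, "reduction", lower = 0, upper = 1)
  lapply(true_mids, function(m) {
    f <- m$fractions
    labeled <- f[-1] * (1 - reduction)
    mid(c(f[1] + sum(f[-1]) * reduction, labeled), metabolite = m$metabolite)
  })
}
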