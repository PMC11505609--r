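---
title: "Methods: multimodal quantification of amyloid pathology phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal quantification of amyloid pathology phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admodal)
```

`admodal` re-implements, as one auditable pipeline, the three quantification
arms used to characterize the 5xFAD transgenic mouse (an aggressive amyloid
model carrying five familial Alzheimer mutations) against wild-type
controls: fluorescence immunohistochemistry (IHC) marker quantification,
^13^C stable-isotope functional metabolic mapping, and diffusion kurtosis
imaging (DKI) of fixed brains — together with the statistical machinery that
ties per-sample readouts into group conclusions. Raw data of this kind are
rarely deposited, so the package pairs every quantification step with a
synthetic generator that produces inputs *with known ground truth*. The
point of the synthetic layer is falsifiability: every number the pipeline
emits can be scored against the truth that generated its input.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do not
demonstrate about real data.

## IHC marker quantification

Markers are quantified per region of interest (ROI) on single-channel
images with a physical pixel size (the study scales: 2.02 µm/px at 5×,
0.5128 µm/px at 20×):

* **positive-pixel percentage** (amyloid-beta, GFAP, IBA1):
  `100 · |mask ∧ roi| / |roi|` after background subtraction and
  binarization;
* **mean grayscale** (MBP/myelin): the arithmetic mean of *raw* intensities
  over the ROI — deliberately computed before any contrast enhancement,
  since a percentile stretch would destroy comparability across images;
* **nuclei density** (DAPI): connected-component count divided by the ROI
  area in mm², `|roi| · pixel_size_um² · 10⁻⁶`.

The processing chain is background subtraction → contrast enhancement →
binarization → labeling, with each step exposed:

* *Background subtraction* is a grayscale morphological opening with a disk
  of radius `radius_px` (default 25 px), subtracted and clipped at zero. A
  flat image maps to zero; objects smaller than the disk survive intact.
  The radius must exceed the largest genuine object.
* *Contrast enhancement* linearly rescales the `[P_low, P_high]` percentile
  window to [0, 1] with clipping (defaults 1–99 when used standalone; the
  nuclei pipeline uses 0–100).
* *Binarization* defaults to Otsu's threshold on a 256-bin histogram
  spanning the data range. Binning over the range (not a fixed [0, 1]
  window) makes the threshold exactly shift-equivariant, which the tests
  exploit. Otsu assumes a bimodal histogram: on a marker-free image it will
  happily split noise in half. The pipeline therefore quantifies marker
  channels with a **fixed threshold** (default 0.3 on the
  background-subtracted scale, the kind of value one calibrates on control
  slices); Otsu remains the default for DAPI, where nuclei are always
  present. The original study's script and thresholds are unpublished, so
  both modes are plain configuration.
* *Labeling* is 8-connected (diagonally touching pixels join), followed by
  an area filter (defaults: minimum 20 px, maximum 10× the median component
  area, rejecting specks and merged clumps) and a centroid-in-ROI rule for
  objects at the ROI boundary. No watershed splitting is applied by
  default, because the upstream description is plain binarization; the
  generator's `allow_touching` flag exists precisely to show what merging
  does to counts.

## ^13^C isotope tracing

A mass-isotopomer distribution (MID) is the vector f₀…f_n of fractional
abundances of the M+0…M+n isotopologues of an n-carbon metabolite. GC–MS
measures MIDs convolved with naturally occurring ^13^C (≈1.07% of carbon);
the analysis must deconvolve this before interpreting tracer enrichment.

The forward model is binomial: a molecule with j tracer-labeled carbons is
observed at M+i with probability `C(n−j, i−j) p^(i−j) (1−p)^(n−i)`, giving
a lower-triangular column-stochastic correction matrix **A**. Correction
solves `min ‖A x − measured‖₂, x ≥ 0` (non-negative least squares via an
active-set solver) and renormalizes, rather than inverting **A** directly —
inversion produces negative fractions on noisy data. `p_natural` defaults
to 0.0107 (terrestrial ^13^C abundance). The correction covers the carbon
skeleton only; contributions of derivatization atoms are out of scope
because the derivative chemistry is not specified in this setting.

Two enrichment statistics are computed from corrected MIDs:

* **MCL** (molecular carbon labeling), the weighted average labeled-carbon
  fraction `Σ i·f_i / n` ∈ [0, 1];
* **M+X percentage**, `100 · f_X`, the readout used when a specific
  labeling route matters (e.g. M+3 lactate for glycolysis, M+2 entry via
  acetyl-CoA, M+5 glutamate from uniformly labeled glutamine).

Group summaries report mean ± SD per genotype per metabolite and an
unpaired pooled-variance Student's t-test (the classical form, not Welch),
mirroring the two-group comparisons of the enrichment figures.

The generator's ground-truth labeling tables are plausible first-turn TCA
enrichments for each substrate — a parameterized toy, not a flux model; no
flux fitting is attempted anywhere. Measurement noise is multiplicative
lognormal (unit mean, CV `noise_cv`, default 2%) because MS abundances are
positive with roughly proportional error.

## Diffusion kurtosis imaging

The DKI signal equation for b-value b and unit direction **n** is

ln S(b, n̂) = ln S₀ − b·D_app(n̂) + (b²/6)·MD²·W_app(n̂),

with `D_app = Σ nᵢnⱼ Dᵢⱼ` (6 unique tensor elements) and
`W_app = Σ nᵢnⱼnₖn_l Wᵢⱼₖₗ` (15 unique elements of the fully symmetric
kurtosis tensor). Units are fixed: b in ms/µm², D in µm²/ms, W
dimensionless. The acquisition scheme is the study's: 5 unweighted images
plus 30 quasi-uniform directions (a Fibonacci spiral here) at each of
b = 0.4, 0.8, 1.5, 2.0 ms/µm² — 125 measurements for 22 parameters.

Fitting proceeds in the standard two stages. The substitution Ŵ = MD²·W
makes the equation linear, so weighted linear least squares on log-signal
(weights = squared predicted signal, the first-order variance correction
for the log transform) initializes the parameters; Levenberg–Marquardt on
the exponentiated model refines them. Stabilizations: non-positive signals
are masked; a non-SPD initial D is projected onto the nearest SPD matrix;
apparent kurtosis on the fit directions is kept in [0, 10] by a soft
penalty (weight 0.1). Non-convergence flags the voxel rather than raising.
Noiseless signals from the model class are recovered to ~10⁻¹² relative,
which is what the acceptance checks assert at 10⁻⁵.

The Rician noise floor of magnitude MRI is removed per sample as
`√max(S² − k·σ², 0)`. Both moment conventions appear in the literature, so
`k` is a config option: `k = 1` is the default, `k = 2` (motivated by
`E[M²] = S² + 2σ²`) is `method = "moment2"`. Denoising and Gibbs-ringing
correction are treated as upstream preprocessing; the volume fitter merely
records whether inputs were declared preprocessed.

Scalar maps: MD = tr(D)/3; FA from the eigenvalues of D; MK is the mean of
the apparent kurtosis `K(n̂) = (MD²/D_app²)·W_app` over a 256-point
spherical spiral, symmetrized over the 8 axis reflections and evaluated in
the eigenframe of D. Two properties motivated this construction. First,
accuracy: the symmetrized spiral agrees with a 10⁵-direction average to
<0.2% on anisotropic tensors (a folded-octant variant tried first was an
order of magnitude worse). Second, exact rotation invariance: evaluating in
the eigenframe with a reflection-closed set makes MK bit-stable under joint
rotation of tensors and gradients, eigenvector sign ambiguity included.
Averaging over the 30 acquisition directions instead is available via
`mk_directions`.

ROI summaries pool all voxels of a (hemisphere-pooled) mask and report the
per-metric mean, the voxel count, and the ROI volume normalized to the
whole-brain mask — the volumetric readout used to adjust for whole-brain
scaling.

**Known bias worth stating plainly:** for tissue that is truly a mixture of
Gaussian compartments, the DKI model is the 2nd-order cumulant truncation.
At this scheme's b_max = 2 ms/µm², fitting a strongly non-Gaussian
biexponential (e.g. isotropic d₁ = 0.5, d₂ = 2.0 µm²/ms at equal fractions,
whose analytic b→0 kurtosis is 3(d₁−d₂)²/(d₁+d₂)² = 1.08) yields MK ≈ 0.80
— about 26% low, with a ~2% MD bias — because the omitted higher cumulants
are large. The bias disappears as the b-range shrinks (the tests verify
recovery within 5% at a quarter of the b-range). This is a property of the
DKI representation at finite b, not of the optimizer; ground-truth MK maps
for mixtures are therefore reported from the analytic cumulants with this
caveat.

## Group statistics

* **ROUT outlier screening** (Q = 1% default): robust center (median),
  robust scale RSDR (68.27th percentile of absolute residuals × N/(N−K),
  K = 1), t-based two-sided p-values at N−K df, and a Benjamini–Hochberg
  step-up at rate Q restricted to the 30% most extreme points. This follows
  the published robust-regression-and-outlier-removal recipe; the exact
  proprietary implementation is not public, so this is a documented
  approximation. An all-identical sample has zero scale and yields no
  outliers by construction. Calibration: ≤5% of clean Gaussian samples
  (n = 12) acquire any flag; a 50σ contaminant is flagged always.
* **Two-way ANOVA** uses type-II sums of squares (unambiguous for the
  near-balanced designs used here); a factor with one level collapses the
  model to one-way. **Tukey's HSD** is computed from the studentized range
  distribution with the Tukey–Kramer standard error, which reduces exactly
  to the pooled t-test via q = |t|·√2 for two groups — a closed-form
  identity the tests assert.
* **Permutational three-way mixed ANOVA**: genotype and age between
  subjects, ROI within subject. Observed F statistics come from the
  balanced split-plot decomposition — between effects against the
  subject-within-cell mean square, within effects against the
  subject-by-ROI residual — and match `aov` with a subject error stratum to
  machine precision. Null distributions respect each effect's
  exchangeability stratum: whole subjects are permuted across group labels
  for between effects; ROI labels are permuted within subject for within
  effects. The p-value is the plain proportion of permuted F values
  strictly exceeding the observed F (no (b+1)/(m+1) correction), exactly as
  the study defines it; the corrected estimator is an option. The engine
  requires equal subject counts per between cell and 10,000 permutations by
  default. Simple main effects re-run the permutation test on each stratum
  of a conditioning factor, collapsing factors that become constant, and
  report single-level strata as skipped.

Design note: several permutation schemes are defensible for mixed designs
(raw-label permutation, residual-based schemes); stratified label
permutation was chosen for being simple and exchangeability-respecting, and
because the acceptance surface is *calibration* — type-I error inside the
binomial band of the nominal α, and rank agreement with parametric p on
Gaussian data — not replication of any particular package's p-values.

## What the synthetic layer shows — and what it cannot

The generators emulate: object counts/sizes/densities on the study's pixel
scales with additive Gaussian camera noise; binomial natural-abundance
convolution with proportional MS noise; multi-Gaussian diffusion with
Rician magnitude noise (per-channel SD = S₀/SNR) on the exact acquisition
scheme; and an additive linear mixed model (genotype × age × ROI with
subject random intercepts) for cohorts. Defaults are chosen to mirror the
study conditions: 2 genotypes × 2 ages × 8 ROIs with 7 subjects per cell
(the study used 6–7 per genotype); 4 replicates per group for tracer
experiments; SNR 50 for diffusion phantoms.

Passing tests therefore demonstrate *algorithmic correctness against known
truth*, not robustness to everything real tissue does: plaque morphology,
spatially varying illumination, partial-volume and exchange effects in
diffusion, flux rerouting in metabolism, and non-Gaussian residuals in
cohorts are all outside the generators' vocabulary (deliberately so — see
the non-goals above). Nuclei are non-overlapping disks by default so that a
count has one right answer; real DAPI fields contain touching nuclei, and
the plain connected-component counter *will* undercount them.

## Problem sizes and runtime choices

Test and acceptance runs use scaled study conditions chosen to keep the
whole suite in the minutes range on one core: 192²–512² px phantoms
(Otsu, opening and labeling are resolution-independent algorithms), 100
phantoms for count-recovery rates, 200 simulated null cohorts at 500
permutations (the analysis drivers use the full 10,000) for calibration
bands, 100 cohorts at 1,000 permutations for the parametric-agreement rank
correlation (finer resolution there because saturated permutation p-values
cannot be ranked), and 1,000 replicates for ROUT operating characteristics.
The binomial 95% band for 200 null simulations at α = 0.05 is the [0.02,
0.09] acceptance window used throughout.
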