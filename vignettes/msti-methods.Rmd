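---
title: "Multisequence thrombus imaging: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisequence thrombus imaging: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msti)
```

## The problem

Deep venous thrombi differ in composition: fresh, fibrin- and red-cell-rich
clots dissolve readily under lytic therapy, while older, organized,
collagen-rich thrombi resist it. Multisequence thrombus imaging (MSTI)
characterizes that composition noninvasively with three contrast-free
quantitative MRI readouts, analyzed slice by slice over a segmented
thrombus:

* **T1 relaxation time (ms)** — shortened by paramagnetic iron degradation
  products as a thrombus organizes; the strongest single discriminator of
  lysable tissue in both the murine and human settings this package models.
* **Magnetization transfer ratio (MTR, %)** — the fractional signal loss
  caused by an on-resonance MT prepulse, a proxy for macromolecular
  (protein/collagen) content.
* **Apparent diffusion coefficient (ADC, 10⁻³ mm²/s)** — water diffusivity
  from the signal decay across diffusion weightings; sensitive to clot
  porosity, and contaminated by flowing blood at high values.

`msti` implements the full analysis chain — parametric map fitting, slice
feature extraction, lysability classification — together with a synthetic
phantom-cohort generator so that every stage is testable end-to-end without
any scan data.

## Signal models and parametric fitting

### T1: three-parameter inversion recovery with Look-Locker correction

The inversion-recovery signal is modelled as

$$S(t) = \left| A - B e^{-t/T_1^*} \right|,$$

with apparent relaxation time $T_1^*$ and the Look-Locker correction
$T_1 = T_1^* (B/A - 1)$. With ideal inversion ($B/A = 2$) the correction is
the identity. The fit is a genuine nonlinear least-squares solution of the
three-parameter model, computed by **variable projection**: for fixed
$T_1^*$ the model is linear in $(A, B)$, so the problem reduces to a 1-D
search over $T_1^*$, solved on a log-spaced grid (40 points, 5–10 000 ms)
followed by golden-section refinement to a relative interval of $10^{-12}$.
This finds the global minimiser without starting-value sensitivity, which
matters when fitting tens of thousands of voxels unattended; the inner loop
is compiled (Rcpp). For magnitude data, **polarity restoration** refits with
the sign of the earliest $k$ samples flipped for every $k = 0,\dots,n$ and
keeps the lowest-residual solution. Voxels whose fit returns $B \le A$ or
$T_1^* \le 0$ (constant signal, background) are flagged invalid rather than
raising errors.

### MTR and ADC

MTR is the voxelwise ratio $\%MTR = (M_0 - M_s)/M_0 \times 100$; voxels
with $M_0 \le 0$ are invalid. ADC uses the standard mono-exponential
estimator $ADC = \ln(S_0/S_i)/(b_i - b_0)$ for two b-values and the
log-linear least-squares slope for more, the unambiguous conventional form
of the decay model. Voxels with non-positive signal, signal below a floor
(default 3× the noise level), or a negative estimate are invalid. The
physiological **exclusion rule** then removes voxels with ADC strictly
above 2.0×10⁻³ mm²/s (flow artifact range); a voxel at exactly 2.0 is
retained, reading "exceeding" strictly. A voxel invalid in *any* map is
dropped from joint slice statistics.

## Lysability prediction

Two cohort presets mirror which combination each setting emphasizes:

* **Mouse: combined cutoffs.** A slice is called lysable iff
  T1 < 784 ms **and** volume-normalized MTR < 2800 %/cm³ **and**
  ADC > 0.88 (10⁻³ mm²/s), all strict, ties conservative (nonlysable). The
  conjunction is the plain reading of a combined operating point; a
  composite-score ROC is a possible alternative but is not implied by a set
  of per-parameter cutoffs.
* **Human: logistic probability.**
  $$P = \frac{e^{\beta_0 + \beta_1 T_1 + \beta_2 ADC}}
             {1 + e^{\beta_0 + \beta_1 T_1 + \beta_2 ADC}},
  \qquad \beta_0 = 5.37,\; \beta_1 = -0.006,\; \beta_2 = -0.448 .$$
  The ADC coefficient is interpreted with ADC expressed in 10⁻³ mm²/s —
  the scale on which all group values are reported — which yields sensible
  probabilities at the group medians (0.81 for lysed vs 0.56 for nonlysed
  medians). No operating threshold is published for the binary call; the
  default is 0.5, with the Youden-optimal threshold from `roc_analysis()`
  available as an alternative. The implementation is numerically stable for
  $|\eta|$ up to at least $10^3$ and clamped to the open unit interval.

`normalize_mtr()` defines volume-normalized MTR as (mean MTR)/(volume in
cm³). The %/cm³ unit is dimensionally ambiguous as printed; this definition
reproduces the unit and the qualitative behaviour (small fresh thrombi
score high), and the 2800 cutoff is therefore treated as cohort
configuration, not physics.

`fit_logistic()` delegates the maximum-likelihood fit to `stats::glm`
(IRLS) — the standard estimator, not a contribution of this package — and
adds Wald intervals, odds ratios, training AUC, a complete-separation flag,
and a singular-design error.

## The synthetic cohort generator

The generator defines the study conditions for every downstream test. It
emulates two-group (lysed vs nonlysed) cohorts whose thrombus T1/ADC/MTR
marginals match the reported group medians and interquartile ranges, with
per-slice heterogeneity and Rician acquisition noise.

**Marginal family.** Each parameter is log-normal — positive, right-skewed,
and exactly parameterizable from a median and IQR:
$\mu = \ln(\text{median})$,
$\sigma = (\ln q_3 - \ln q_1) / (2 z_{0.75})$ with $z_{0.75} = 0.6744898$.

**Truncation-aware ADC calibration.** The reported ADC summaries describe
data *after* the 2.0 exclusion. For the human nonlysed group
(1.23 [0.69–1.74]) a naive log-normal places ≈24 % of its mass above 2.0,
and the pipeline's own exclusion would then shift the recovered median far
below the calibration target. ADC marginals are therefore calibrated so
that the log-normal **conditioned on ADC ≤ 2.0** has exactly the target
median, with quartiles matched in least squares; sampling draws from that
truncated law. When the reported upper quartile lies close to the bound the
family saturates — no $\sigma$ reproduces the quartiles exactly — so
$\sigma$ is capped at 1.5 and the quartile fit is best-effort while the
median remains exact. For distributions with negligible mass above the
bound this reduces to the closed form.

**Latent organization score.** With `latent_correlation = TRUE` (default),
each subject draws one latent "organization" score; T1, ADC and MTR are
monotone quantile transforms of it with configured signs: T1 and MTR rise
with organization in both cohorts, ADC falls with organization in the mouse
cohort but rises in the human cohort, matching the observed group
contrasts. Within-thrombus heterogeneity adds a slice-level jitter on the
latent scale, scaled per parameter so each parameter's within-thrombus
coefficient of variation is approximately `slice_jitter_cv` (default 0.10 —
no within-thrombus dispersion is reported anywhere, so this is a free
parameter chosen to make heat maps visibly heterogeneous). Mapping jitter
through the (possibly truncated) quantile function keeps every draw inside
the support and leaves medians unchanged.

**Stratified subject latents.** By default subject-level latent scores are
drawn by stratified (Latin-hypercube-style) sampling, so a 40-subject group
is quantile-representative of its configured distribution; group medians of
small cohorts then converge at $O(1/n)$ rather than $O(1/\sqrt n)$. This is
a variance-reduction design choice for reproducible cohort studies; plain
iid draws remain available (`stratify_subjects = FALSE`) and are used for
the marginal-distribution tests.

**Mouse MTR.** No mouse MTR group summaries are reported (the groups did
not differ), so both groups share a nominal 40 [35–45] % distribution, and
the phantom geometry (≈0.025 cm³ thrombus) places volume-normalized MTR
near 1600 %/cm³ so the <2800 cutoff is almost always satisfied. Mouse MTR
is generator plumbing, explicitly non-reproducing.

**Acquisition.** Geometry is a cylindrical vessel with a contiguous
thrombus (mouse: 0.25×0.25×0.5 mm voxels; human: 1×1×2 mm). Defaults: 8
log-spaced inversion times 100–5000 ms (a generic IR series exercising the
same three-parameter fit as a clinical MOLLI scheme, whose exact timings
vary); b-values {0, 600} s/mm² (a conventional body-DWI choice with
adequate ADC precision at the default SNR); ideal inversion $B/A = 2$;
Rician noise at SNR 40 ($\sigma = A/40$). All are configurable. Vessel
lumen is assigned diffusivity 3.0×10⁻³ mm²/s so flowing-blood voxels are
caught by the ADC exclusion, as in real data. Every random stage draws from
a named substream derived from the root seed; identical configurations are
bit-identical.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: no k-space or sequence physics beyond the
three signal models, no motion, flow or partial-volume artifacts, no
registration error between sequences (stacks are generated co-registered,
as the analysis assumes), no anatomic variation in thrombus shape, and no
within-subject correlation structure beyond the single latent score. Tests
passing on this generator validate the *computational* chain, not the
biology.

## Evaluation properties instead of irreproducible operating points

The published diagnostic performance (mouse 88 %/97 %; human 86 %/91 %;
AUC 0.847) and interobserver statistics (r = 0.92/0.88/0.94, κ = 0.66)
depend on the unavailable raw cohorts and on within-subject correlation
structure that group medians and IQRs do not determine. Under this
generator's conditions the mouse conjunction attains a sensitivity near
76 % — the comonotone upper bound $\min_k \text{sens}_k$ given the
marginals — so those operating points are *not* desk-reproducible, and the
package does not tune toward them. The acceptance suite instead checks
structural properties: the conjunction classifier beats the least
informative single cutoff on Youden's J (sensitivity and specificity
summarized jointly; a conjunction containing an almost-always-satisfied
cutoff cannot beat that cutoff's sensitivity alone, so J is the meaningful
scalar), and is at least as specific as every single cutoff; the
trapezoidal AUC equals $U/(n_1 n_2)$ on arbitrary tied data; the
conjunction equals its brute-force evaluation; and all hand-computed
statistics examples hold exactly.

## Statistics suite conventions

* **Mann-Whitney U**: midrank ties; exact two-sided p by enumerating the
  permutation distribution of the rank sum (a subset-sum dynamic program
  over doubled midranks, valid under ties) when $n_x n_y \le 400$,
  otherwise normal approximation with tie and continuity corrections;
  two-sided p is $2\min(\text{tail}, 0.5)$.
* **ROC**: thresholds at midpoints between sorted unique scores; Youden
  ties broken toward higher specificity (fewer false positives).
* **Bland-Altman**: bias ± 1.96 sample SD of differences. **Cohen κ** from
  marginal products; undefined at chance agreement 1.
* No multiple-testing correction is applied anywhere, matching the
  analysis the package reproduces.
* Wald confidence intervals only; profile and DeLong intervals are out of
  scope.

## Problem sizes and tolerances used by the tests

The suite validates at the study's own scale: coefficient recovery uses
5000 simulated slices per replicate; the cohort roundtrip uses 40 subjects
per group per cohort (10 slices each) at SNR 40 and requires recovered
group medians within 3 % of their calibration targets; the noiseless
roundtrip requires every fitted map to equal ground truth within 0.1 %
(it achieves ~10⁻¹⁴ relative error); T1 median bias at SNR 40 is required
below 2 % over 400–1200 ms. The full suite runs in well under two minutes
on one CPU.

## Known limitations

* The slice-level dispersion, voxel-level texture, and T1–ADC rank
  correlation of real thrombus are unknown free parameters of the
  generator; only the group marginals are calibrated.
* The truncated ADC family cannot reproduce the human nonlysed upper
  quartile exactly (see above); the median is exact.
* The univariate odds ratio for T1 (0.988) and the multivariate
  $\beta_1 = -0.006$ describe different fits of data this package cannot
  access; no attempt is made to reconcile them.
* Masks are inputs; there is no automatic thrombus segmentation, no image
  registration, and no DICOM ingestion.

## A worked example

```{r example, eval = FALSE}
cc <- msti_cohort_config("human", n_subjects = 4, seed = 3)
sub <- simulate_subject(cc, "lysed", 1)
maps <- compute_maps(sub$stack, sub$mask_thrombus)
feats <- extract_slice_features(maps, sub$mask_thrombus,
                                subject_id = "lysed_01",
                                outcome_label = "lysed")
preds <- predict_lysis(feats, "human-logistic")
probability_heatmap(preds, sub$mask_thrombus,
                    out_prefix = file.path(tempdir(), "subject01"),
                    voxel_size = sub$stack$voxel_size)
```

The same chain, over whole cohorts and with manifests, is
`run_pipeline(msti_pipeline_config(...))` or the `inst/scripts/msti.R`
command line.
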