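---
title: "Multi-reader multi-case analysis of prostate MRI CAD reader studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-reader multi-case analysis of prostate MRI CAD reader studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promrmc)
```

## The study this package models

promrmc implements the statistical machinery of a two-session,
multi-reader multi-case (MRMC) prostate MRI reader study: nine radiologists
(six highly, three moderately experienced) read a cohort of 144 case and 72
control patients twice — once as conventional multiparametric MRI (mpMRI)
interpretation under PI-RADSv2, once assisted by a computer-aided diagnosis
(CAD) probability map — recording up to four lesions per patient per session,
each with a sector location (zone, side, level) and a PI-RADSv2 category 1–5.
Ground truth comes from whole-mount prostatectomy pathology in cases and
saturation biopsy in controls. The package covers the design (hybrid
reader–case allocation and its power), the measurement model (lesion
matching, index lesions, performance tables, ROC/AUC), inference
(disease-stratified bootstrap with Wald tests), inter-reader agreement (index
of specific agreement), and the computed high-b diffusion preprocessing step.
Because reader-study data of this kind are rarely shared, a first-class
synthetic-data generator reproduces the cohort's statistical structure so the
whole pipeline is testable end to end.

## The hybrid design and its power

Reading every patient by every reader would cost each reader 216
interpretations per session. The hybrid design cuts this: a randomly chosen
common subset (one sixth, stratified by disease status, i.e. 24 cases + 12
controls) is read by all nine readers, and each remaining patient is read by
exactly one of the $\binom{9}{2} = 36$ reader pairs. Total interpretations
are then $36 \times 9 + 180 \times 2 = 684$, a mean of exactly 76 per reader
with a 2:1 case:control mix — identities that hold for any seed and that
`allocate()` reproduces exactly.

A design point worth making explicit: the per-reader load *range* stays
narrow (roughly 75–78) only if the pair blocks are balanced. Assigning each
of the 180 residual patients to a uniformly random pair would give each
reader a Binomial(180, 2/9) share with standard deviation near 6, i.e.
realized loads spread over roughly 60–95. `allocate()` therefore defaults to
balanced randomization — block sizes within each stratum differ by at most
one, with the patient order and the placement of the larger blocks both
random — and offers `balance = FALSE` for fully independent uniform draws.

The endpoint is the difference in average reader-specific index-lesion
sensitivity between sessions. `power_z()` uses a deliberately simple variance
model: independent binomial variation at the baseline sensitivity $p_1$ and
the improved $p_1 + \delta$ over each reader's case readings, averaged over
readers,
$$\mathrm{Var} = \frac{1}{R^2}\sum_r \frac{p_1(1-p_1) + p_2(1-p_2)}{m_r},$$
ignoring the correlation between readers induced by the shared common subset
and any within-patient correlation across sessions. `power_sim()` simulates
the full design (allocation, per-reading Bernoulli detections at $p_1$ and
$p_1+\delta$, Z test with the plug-in standard error) precisely to quantify
what that approximation misses; the test suite checks the two agree within
Monte-Carlo error over a grid of $(p_1, \delta)$ and that the simulated
rejection rate at $\delta = 0$ matches the nominal level. For the study
design ($p_1 = 0.76$, $\delta = 0.10$) both land near 0.97; we report the
analytic and simulated values side by side rather than asserting any single
printed number, since the exact variance formula behind a published power
claim is rarely recoverable.

## Ground truth, index lesions, and matching

Lesions live on a discrete 12-sector grid (zone PZ/TZ × side left/right ×
level apex/mid/base); a lesion may span both zones, in which case it carries
both zone tags and occupies both sectors. The *index lesion* of a patient is
the lesion with the highest Gleason score and largest volume, ordered
lexicographically by Gleason total, then primary pattern (4+3 beats 3+4),
then volume; an exact tie on all three demands an explicit flag rather than
an arbitrary winner.

`match_findings()` links reader findings to lesions by exact agreement on a
configurable subset of the sector key (all three components by default). In
the source study, co-localization was adjudicated with annotated screenshots;
that cannot be coded, so the exact sector key is an explicit package
convention. Each finding is assigned to at most one lesion — index lesion
first, then descending Gleason, then volume — and when several findings land
on one lesion the highest score is kept. Unmatched findings are false
positives; matched plus unmatched always equals the total, and matching is
order-invariant. A brute-force per-finding enumerator in the test suite
verifies the vectorised implementation on random configurations.

## Performance measures

Patient-based analysis uses the maximum PI-RADSv2 score a reader assigned to
a patient (0 when nothing was recorded, so threshold ≥ 1 means "any recorded
lesion"). Sensitivity at threshold $t$ is the fraction of case readings with
score ≥ $t$; specificity the fraction of control readings below $t$. The
package's estimand is the unweighted mean of reader-specific proportions
("average reader-specific sensitivity"); a pooled reading-weighted variant is
available via `average = "pooled"`. The empirical ROC sweeps the thresholds
and `empirical_auc()` returns the trapezoidal area, which equals the
Mann–Whitney statistic with half-credit for ties (verified against an
$O(n^2)$ pairwise oracle). Lesion-based analysis reports index-lesion
sensitivity for the whole prostate and per zone; a both-zone index lesion
counts in both the PZ and TZ strata. Clinically-significant-cancer analyses
are a Gleason filter (`min_gleason = 7` for ≥ 3+4) on the same code path,
not a separate one. AUC is computed on pooled readings by default; whether
one pools or averages per reader is genuinely open, so both are provided.

## Inference: stratified bootstrap and Wald tests

`stratified_bootstrap()` resamples case patients within the case stratum and
control patients within the control stratum, never across; readers are fixed.
Each drawn patient carries its complete record — lesions plus all readers'
findings in both sessions — so paired session differences are computed on
identical resampled patient multisets within every replicate. Confidence
limits are the 2.5th/97.5th percentiles of the replicates; the interpolation
convention is pinned to R's default type-7 quantile so results are exactly
reproducible. Intervals are percentile (not BCa) and no multiplicity
correction is applied across table cells, matching standard practice for
this design. `wald_diff_test()` forms $z = \hat\Delta / \mathrm{sd}(\Delta^*)$
with a two-sided normal p-value; a zero bootstrap SE is flagged rather than
divided. The suite checks percentile coverage of a sample mean (500 datasets
of 200 patients at $b = 500$, target band 93–97%) and the Wald type-I rate on
400 null studies (band 3–8% at $\alpha = 0.05$).

## Index of specific agreement

For lesion detection there is no meaningful "negative" cell, so chance-
corrected kappas are inappropriate; agreement is the index of specific
agreement: the conditional probability that a second reader reports a finding
at the same sector as a randomly selected reader. Over all ordered reader
pairs in a pairing stratum (overall, high–high, moderate–moderate,
high–moderate) and every patient both read, the denominator counts the
locations the first reader reported and the numerator those the second also
reported (any score — the table is about detection, not grading). Counts are
pooled over pairs and patients before the ratio, which is robust to patients
with no findings and corresponds to detection-weighted selection of the
random reader; a per-pair average is available behind a flag. For two raters
this reduces exactly to positive specific agreement $2a/(2a+b+c)$. Findings
on control patients count by default (agreement on a false positive is still
agreement on detection) and can be switched off. `isa_all()` evaluates all
strata in one vectorised pass through per-(patient, location) reader-class
counts; the tests prove it identical to the plain ordered-pair enumerator.

## Computed high-b diffusion imaging

CAD processing needs a b = 1500 s/mm² diffusion image; when the scanner did
not acquire one it is synthesized from the mono-exponential model
$S(b) = S_0 e^{-b\,\mathrm{ADC}}$. `fit_adc()` fits by ordinary least squares
in log-signal space — exact for the two-b-value case
($\mathrm{ADC} = \ln(S_1/S_2)/(b_2-b_1)$) and the standard choice for the
few-b-value protocols involved; weighted fits would add nothing at two
points. Non-positive voxels are masked. `synthesize_high_b()` evaluates the
model at the target b; negative fitted ADCs (pure noise) are clamped to zero
*at synthesis only*, with a count, so the fitted ADC map itself remains
diagnostic of noise. `generate_dwi_phantom()` provides grids with stored
ground truth; noiseless round trips recover $S_0$ and ADC to below $10^{-9}$
relative error. No IVIM or kurtosis terms, and no inter-sequence
registration, are modelled.

## What the synthetic generator does and does not emulate

`sim_config()` defaults encode the study conditions:

* **Cohort**: 144 cases + 72 controls; lesion counts per case are
  zero-truncated Poisson with mean 1.98 (the published per-patient mean; the
  underlying rate is solved numerically, and a mean of 1 degenerates to one
  lesion per case). The zone mix is 187:88:10 (PZ : TZ : both) of 285.
  Gleason patterns follow a mix centred on Gleason 7 with a 3+3 minority;
  volumes are log-normal (median 0.5 ml). Expected total lesions for 144
  cases: 285.1.
* **Readers**: 6 high + 3 moderate experience. Detection probabilities per
  (zone, session, experience) default to the reported zone-by-experience
  index-lesion sensitivities at threshold ≥ 1 (MRI: PZ 0.86/0.80,
  TZ 0.73/0.67 for high/moderate; CAD: PZ 0.772/0.777, TZ 0.762/0.835). A
  both-zone lesion is detected with the larger of its two zone probabilities.
* **Scores**: detected true lesions draw a score from a per-session
  distribution whose mass above 3 matches the observed ratio of
  threshold-3 to threshold-1 sensitivity in each session.
* **False findings**: Poisson per patient and session, placed on sectors not
  occupied by a true lesion (so they never collide with ground truth under
  exact-key matching), with a decreasing score distribution. The MRI rate
  (0.7958) is calibrated so the pooled patient-level MRI sensitivity at
  threshold ≥ 1 is 0.956, which makes the implied MRI specificity at
  threshold 1 about 45%; the CAD rate (1.0642) and score distribution are
  calibrated to CAD patient-level specificity 34.5% at threshold 1 and 71.5%
  at threshold 3. A Poisson false-finding process with a decreasing score
  distribution cannot simultaneously reproduce every published specificity
  cell — in particular the MRI threshold-3 specificity comes out near 68%
  rather than ~45% — and we prioritise the sensitivity calibration because
  the recovery tests assert it. `theoretical_patient_perf()` gives the exact
  operating point implied by any configuration and serves as the oracle for
  the calibration tests.
* **Cap**: at most 4 findings per reader-patient-session; lowest scores are
  dropped first, true-lesion findings surviving ties.

Not emulated: institution or scanner effects, within-patient correlation of
detections across sessions or readers (detections are conditionally
independent given the lesion configuration), reader-specific bias beyond the
experience classes, score dependence on Gleason or volume, and reading-time
behaviour. Passing recovery tests therefore demonstrate that the *analysis*
machinery is correct and calibrated under a known generative process — they
do not certify performance claims about real readers, whose correlation
structure is richer.

## Numerical conventions and test problem sizes

Per-stage seeds derive from one master seed as
$(48271 \cdot s + k) \bmod (2^{31}-1)$, exact in double precision, so partial
re-runs are reproducible; `run_study()` writes the full seed chain, a config
hash and every table to its output directory, and two runs with the same
master seed are byte-identical. The test suite sizes simulations for a
single-CPU desk run: 1000 random configurations for each exact oracle
(ISA and AUC), 500 × 500 bootstrap replicates for coverage, 400 null studies
at $b = 150$ for the Wald size, 2000 replicates per point for the power
grid, and cohorts of 200–500 patients for calibration recovery — large
enough that 3–4 Monte-Carlo SD bands are decisive, small enough to finish in
minutes.

## Known limitations

Bilateral or midline location labels are outside the sector vocabulary and
must be pre-mapped before import. The exact-key matching convention is
stricter than human screenshot adjudication, so real-data sensitivities may
shift slightly relative to an adjudicated analysis with identical readings.
The power variance model excludes between-reader correlation; `power_sim()`
is the honest check. Lesion-level specificity is not estimated (no negative
regions are defined), matching the design's validation scheme.
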