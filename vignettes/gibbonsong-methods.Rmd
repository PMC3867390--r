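---
title: "Methods: individuality, androgens and age in simulated gibbon solo songs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individuality, androgens and age in simulated gibbon solo songs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

Male white-handed gibbons (*Hylobates lar*) give loud solo songs built from
frequency-modulated notes ("elements") grouped into "calls". The analysis
chain implemented here asks three questions of such songs: do calls carry an
individual signature; does call pitch track a male's fecal androgen level;
and do call timing parameters differ with social status or age class. The
package implements every stage — acoustic measurement, factor analysis,
permuted discriminant function analysis (pDFA), hormone matching, and mixed
models with a temporal-autocorrelation covariate — together with a
synthetic-data generator that produces audio and hormone series with known
ground truth, so each stage can be tested quantitatively without field
recordings.

## The synthetic-data generator

`simulate_truth()` builds a full study: a population of males allocated to
pair-living and multimale groups (`simulate_population()`), a recording
schedule of dawn sessions, songs synthesized as element trains
(`synthesize_song()`), and per-male fecal androgen series
(`simulate_androgen_series()`).

Songs are rendered at 8 kHz as sums of frequency-modulated sinusoids. Each
element sweeps from its start frequency up to a maximum located in the final
third of the element (a half-cosine rise, then a shallow decay to an end
frequency close to the maximum), so that start F0 < end F0 ≈ max F0 — the
ordering seen in field measurements of this species (median start around
700 Hz, end and max around 950 Hz for adults). Element durations (median
0.27 s), inter-element intervals (median 0.54 s, all below 4.5 s), and
element counts per call (3–50) are drawn from log-normal and negative
binomial distributions spanning the published field ranges. Calls are
separated by silences of at least 6.5 s, so the 5 s segmentation gap
separates calls from intervals unambiguously. Broadband Gaussian noise is
added at a configurable SNR (40 dB by default; tests of measurement accuracy
use 60 dB).

The injected structure the analysis must recover:

* **Androgen → pitch, between males.** Each male's mean androgen level is
  log-normal across the population; his baseline pitch is
  `f0_center + f0_sd * (effect_androgen_pitch * z + noise)`, with
  `effect_androgen_pitch = 0.5` pitch SDs per SD of log androgen level.
* **Age → call duration.** Senior males' element and interval durations are
  scaled by `effect_age_callduration = 0.75`, shortening their calls
  multiplicatively (a motivational-pacing reading of the age effect).
* **Excretion lag.** The androgen level that drives a recording day's pitch
  appears, by construction, as a fecal sample collected three days later, so
  every recording day has an in-window sample and the matcher can be tested
  against known assignments.
* **Day-scale residual autocorrelation.** Per male, a Gaussian-process
  residual with squared-exponential covariance of bandwidth
  `ac_sigma_true = 2` days perturbs day-level pitch.

Recording schedules are drawn as consecutive-day bouts (spacings of 1–3
days), matching the field practice of teams following a group daily for a
stretch; with schedules scattered weeks apart, day-scale autocorrelation
would be invisible in any analysis.

`simulate_call_features()` and `simulate_model_table()` are fast
feature-level and model-level generators for the discriminant and
mixed-model stages; they skip audio entirely. `simulate_model_table()`
standardizes the between-male androgen scores to sample mean 0 / SD 1: the
male panel is a fixed condition of the study design, and re-drawing it would
confound variation in panel strength with the behavior of the analysis under
test. Its noise defaults (`sd_male = 0.08`, `sd_group = 0.08`,
`sd_date = 0.12`, `sd_song = 0.1`, `sigma_ac = 0.15`, `sigma_e = 0.3`) are
calibrated so that the fixed 0.5-SD between-male androgen effect carries the
same order of statistical strength in a 13-male study as the corresponding
reported real-data result; with male-level noise much larger than this, no
method can recover the effect from a dozen subjects.

What the generator deliberately does **not** emulate: gibbon timbre and
harmonics (elements are pure FM tones), duets and female great calls,
background biophony, recording-chain variation, or assay error in the
hormone values. Passing tests therefore demonstrate that the analysis chain
recovers known structure from data satisfying its assumptions — not that it
is robust to every nuisance of real field recordings.

## Acoustic measurement

`compute_spectrogram()` uses a 256-point Hamming-window FFT with 50% overlap
at 8 kHz: 31.25 Hz bin spacing and a 16 ms hop. Input at other rates is
resampled with an anti-aliased polyphase filter first. Element detection
(`extract_elements()`) marks a frame as signal when the peak magnitude
inside the F0 search band (100–2000 Hz) is within `threshold_db` of the
recording's peak; the default −12.8 dB sits centrally in the −5 to −20 dB
range used in practice, and runs shorter than 2 frames are discarded as
sub-resolution artifacts. Per frame, F0 is the frequency of the
maximum-magnitude bin — valid for gibbons, whose fundamental carries the
highest amplitude. `measure_element()` takes start/end F0 from the first and
last frames, max F0 at its first attainment (the tie rule that makes the
relative location of a flat contour 0), and duration as the frame-time span.
`aggregate_call()` emits call duration plus mean, maximum and variation of
the seven element measures — 22 parameters. "Variation" is the sample
standard deviation by default (coefficient of variation available);
single-element calls have no intervals and no variation, carry `NA` there,
and are flagged and later dropped listwise.

On near-noiseless synthesized songs the whole chain round-trips: element and
call counts equal the annotation, durations agree within two hops, and F0
measures within one frequency bin (the test suite asserts exactly these
tolerances).

## Factor analysis

Transformations follow a fixed per-parameter map (log for durations and
interval maxima, square root for the variation block and max-F0 location,
`sqrt(x - min(x))` with the training-data minimum frozen for the left-bounded
interval and F0 maxima). Natural logarithms are used; the base only rescales
columns and leaves an analysis of the correlation matrix unchanged.
Sampling adequacy is reported as Bartlett's sphericity test (df = p(p−1)/2,
231 for 22 parameters) and the Kaiser–Meyer–Olkin statistic computed from
the anti-image partial correlations. Extraction is by principal components
of the correlation matrix — the default of the commercial software
historically used for such tables — with factors retained while their
eigenvalue exceeds 1 and varimax rotation under Kaiser normalization
(maximum-likelihood extraction is deliberately out of scope). Scores use the
regression method, `W = R⁻¹Λ`, and are exactly mean-zero over the fitting
data. On tables built from six orthogonal planted factors plus noise
(SD ≤ 0.2), the model recovers rank six with every parameter loading ≥ 0.5
on its generating factor.

## The permuted DFA

Calls from one recording day are not independent, so classical DFA
significance would be anticonservative. The test here: every male with more
than `n_select` calls contributes exactly `n_select = 23` randomly chosen
calls (one more than the parameter count) to derive linear discriminant
functions; held-out calls are assigned to the nearest class centroid in the
Mahalanobis metric of the pooled within-class covariance (equal priors — the
balanced design makes them natural); the observed statistic averages the
percent correct over 100 selections. Significance comes from 1,000
restricted permutations in which whole male-day blocks of calls are
reassigned to males, preserving each male's day count; the observed
arrangement counts as one permutation, so the smallest attainable p is
1/1,000, and ties count as exceedances. The LDA is implemented directly
(Cholesky sphering, ridge-regularized when the covariance is rank-deficient)
because it sits inside a 100 × 1,000 loop; the test suite cross-checks its
assignments against the classical implementation in `MASS::lda`.

Two calibration points from simulation: with matched selection counts for
the observed and permuted statistics, the type-I error under an
exchangeable, day-correlated null sits near the nominal 5%; computing fewer
selections per permutation (`perm_selections`) makes permuted statistics
noisier than the observed one and the test measurably conservative — the
fast mode is available, but null calibration is checked in matched mode.

## Hormone matching and centering

Day 3 after a recording is taken as the optimal excretion day; samples
collected 0–7 days after the recording are eligible, those minimizing the
distance to day 3 are chosen, and equal-distance ties are averaged (the
"closest to the optimal day" reading; lag distances are calendar days, since
collection and recording times do not resolve finer). Songs without an
in-window sample are excluded, not imputed. Matched values are z-transformed
globally, then split into a per-male mean (between-subject term) and the
within-male deviation; the decomposition `z = between + within` is exact and
the within term has mean zero per male by construction.

## Mixed models with the autocorrelation term

Each factor score is modeled with Gaussian `lme4::lmer` fits: fixed effects
status (pair-living reference), age (adult reference; subadults excluded),
androgen between- and within-subject terms; random intercepts for group,
male, date within male, and song (nested in male-date — each song belongs to
one male on one day); and a random within-androgen slope by male, fitted
without intercept–slope correlation by default (a dozen subjects carry
little information for that correlation). Factors that lose their second
level in a data subset are dropped with a warning rather than failing.

Temporal dependence is absorbed by the autocorrelation term: for call *i* of
male *m*, the Gaussian-kernel weighted average of the male's other
conditional residuals from the no-AC model,
`AC_i = Σ_{j≠i} w_ij r_j / Σ w_ij` with
`w_ij = exp(−(t_i−t_j)²/(2σ²))`, z-transformed before entering the model.
The bandwidth σ is chosen to maximize the ML likelihood of the refitted
model over a log-spaced grid refined by golden-section search; ML is used
throughout the search for comparability, and the selected model is also
refit by REML for variance components. The term is built once from the no-AC
residuals (`iterate_ac` repeats to convergence if wanted).

Three numerical properties of this construction, established during
development and reflected in the defaults:

* **Upper grid bound.** The grid runs from the smallest positive within-male
  lag up to a quarter of the median within-male observation span. Beyond
  that the kernel is nearly flat within males, and the leave-one-out
  weighted average degenerates toward `const − r_i/(n−1)` — a linear
  function of the observation's own residual that, after the z-transform,
  produces a spurious likelihood rise with σ running to the ceiling.
* **Residual type.** The term is built from conditional residuals. Marginal
  (fixed-effects-only) residuals retain the male-level effect, and the term
  then absorbs precisely the between-male information the androgen test
  needs. Conditional residuals leak across observations only through BLUP
  shrinkage within very small date/song groups (with two calls on a day,
  their conditional residuals are strongly anti-correlated); with realistic
  numbers of calls per day this coupling is weak.
* **Identifiability and the null.** The bandwidth is statistically
  identifiable only when same-day replication is modest: with many calls per
  day, the same-day average predicts the day level so well that the ML
  bandwidth collapses to the within-day scale whatever the true day-scale
  bandwidth. The recovery simulation therefore uses a sparse design (one
  call per day over ~20-day bouts), where the estimated bandwidth lands
  within a factor of two of the truth (median over replicates). Under
  independent residuals the likelihood profile is flat and the gain from the
  term small, several-fold smaller than under genuine autocorrelation — but
  the Wald t of the term itself is **not** a valid null statistic: the
  bandwidth is selected to maximize the very likelihood the t is computed
  from, and the z-transform amplifies residual mechanical correlations.
  Significance claims about the autocorrelation term should rest on nothing
  here; the term is a nuisance control.

Fixed-effect p-values are likelihood-ratio tests of the full against the
dropped-term model (both fitted with two optimizers, keeping the better
likelihood — the default optimizer occasionally stalls in a local optimum
and would otherwise produce spurious LR statistics). A parametric-bootstrap
mode (`method = "bootstrap"`, default 1,000 simulations from the reduced
model) replaces the historical MCMC p-values with a reproducible
finite-sample alternative; the asymptotic path is the default in the
analysis scripts for runtime. Per predictor, p-values are Simes-adjusted
across the factor-score models by the step-up rule
`p̃_(i) = min_{j≥i} (m/j) p_(j)` (computed via `stats::p.adjust`'s "BH"
method, which implements the identical formula; a direct-formula oracle in
the tests confirms equality). Leave-one-subject-out stability refits the
model once per excluded male, re-searching the bandwidth each time, and
reports each coefficient's range.

## Orchestration and problem sizes

`run_full_analysis()` chains every stage under one `run_config()` seed and
writes stage artifacts plus a manifest of row counts and exclusions (calls
in = calls scored + calls excluded, with reasons: subadult, degenerate
zero-variation parameters, single-element calls). Descriptive tables use
linear-interpolation quartiles (R's default type 7). Determinism is
end-to-end: one master seed, with stage seeds derived by fixed offsets, so a
rerun reproduces every output byte-identically.

Problem sizes in the shipped tests and scripts are the package's choices for
a fast, reproducible demonstration: the simulated study uses 14 males,
40-odd songs and 600–800 calls; the pDFA acceptance computation runs the
full 100 selections × 1,000 permutations; property simulations use 20–200
replicates at reduced permutation counts; mixed-model simulations use
coarser bandwidth grids (3–10 points) than the 25-point default.

## Known limitations

* The acoustic front end assumes tonal, high-SNR signals; there is no noise
  reduction, harmonic tracking, or cepstral pitch estimation.
* The eigenvalue-greater-than-one retention rule is kept for fidelity; on
  weakly structured data it over-extracts relative to, e.g., parallel
  analysis (out of scope).
* The autocorrelation term's caveats above: bandwidth identifiability
  requires sparse same-day sampling, and its own significance is not
  interpretable.
* The generator's effects are linear and Gaussian on the transformed scales;
  it cannot probe robustness to outliers, heteroscedasticity, or assay
  nonlinearity.
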