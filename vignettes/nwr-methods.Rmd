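---
title: "Automated NWR threshold measurement: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated NWR threshold measurement: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwreflex)
```

## The measurement problem

The nociceptive withdrawal reflex (NWR, also called the RIII reflex) is a
polysynaptic spinal reflex that withdraws a limb from a painful cutaneous
stimulus. Its threshold — the lowest stimulus current that reliably evokes
the reflex — is used as an objective probe of spinal nociceptive
excitability, for instance when asking whether a chronic-pain condition
involves spinal sensitization. `nwreflex` implements an automated,
observer-independent version of this measurement: a windowed Z-score
criterion decides from stimulus-locked surface EMG whether a reflex
occurred, and an adaptive staircase drives the stimulus intensity to
bracket the threshold. Because validating such a measurement on patients is
not possible in software, the package pairs the measurement loop with a
synthetic subject simulator so that the whole chain — latent threshold →
EMG → detection → staircase → threshold estimate → cohort statistics — can
be exercised and checked end to end.

## Reflex detection: the windowed Z-score

For each stimulus the detector reduces the EMG sweep to two windows defined
relative to the onset of the stimulus train:

* **baseline**: −60 to 0 ms, characterised by its mean \(m\) and standard
  deviation \(s\);
* **response**: 90 to 150 ms, characterised by its maximum amplitude
  (peak) \(A\) — the latency band in which the reflex burst is expected
  given Aδ-fibre conduction.

The response statistic is the Z-score \(Z = (A - m)/s\), and a reflex is
declared when \(Z \ge 12\), boundary inclusive. The criterion value 12 is
deliberately extreme: under Gaussian baseline noise the peak of a 60 ms
response window sits around 2–3 baseline SDs, so crossing 12 SDs by chance
is essentially impossible (the tests confirm 0 false calls in 10,000 null
sweeps), while a genuine reflex burst is an order of magnitude larger than
baseline noise.

Numerical conventions that the tests pin down:

* Windows are converted from milliseconds to sample indices with
  `floor(t * fs / 1000)` and taken half-open `[start, end)`, so the window
  sample counts are exactly reproducible at any sampling rate (120 samples
  per window at 2000 Hz).
* The baseline SD uses the sample estimator (divisor \(N-1\)); a
  `sd_divisor = "n"` option provides the population estimator since
  conventions differ between acquisition packages.
* The signal is *not* rectified by default — the criterion is applied to
  the raw peak amplitude — but `rectify = TRUE` is available because much
  of the reflex-EMG literature rectifies before peak-picking. Rectification
  matters only for bursts whose largest excursion is negative-going.
* A flat baseline (SD = 0) is a hard error, never a silent "no response":
  a degenerate baseline means the recording, not the subject, failed.
* The Z-score is invariant under amplitude offset and positive rescaling
  of the sweep, which the suite checks to 1e-12 relative.

## The staircase

The stimulus schedule is a three-success staircase over a 0–30 mA range:

1. ascend from 1 mA in 2 mA steps until the first reflex (**success 1**);
2. descend in 1 mA steps until the reflex disappears;
3. ascend in 0.5 mA steps until the second reflex (**success 2**);
4. descend in 0.5 mA steps until it disappears;
5. ascend in 0.5 mA steps until the third reflex (**success 3**).

The reported threshold is the arithmetic mean of the three success
intensities. The run ends early if the 30 mA cap is reached without a
response (`CAP_REACHED`) or if the subject asks to stop (`ABORTED`, raised
by the responder through `abort_session()`).

Decisions taken where the schedule narrative leaves room:

* **Which stimuli count as successes.** Only the three *phase-terminating
  ascending* responses are averaged. Responses evoked while descending
  simply continue the descent; they are real reflexes but they are not
  among the three counted successes.
* **The 30 mA cap.** A required intensity above the cap is clamped to
  30 mA and delivered once; failing at a clamped 30 mA terminates the run.
  (The stimulator hardware can reach 32 mA, but 30 mA is the procedural
  stop.)
* **The 0 mA floor.** A descent that would cross 0 mA treats the floor as
  a guaranteed non-response *without* delivering a stimulus — no stimulus,
  no reflex — and hands over to the next ascending phase at 0.5 mA. This
  resolves the pathological responder whose reflex never disappears.
* **Integer arithmetic.** Intensities are held in integer tenths of mA
  internally. Every reachable intensity is a multiple of 0.5 mA, and the
  integer representation makes that exact: no accumulation of 0.1-ulp
  floating-point drift over ±0.5/±1/±2 steps.

The state machine is verified against an independently written
straight-line transcription of the schedule (no shared code) for all 296
deterministic latent thresholds on the 0.1 mA grid up to 29.6 mA; the two
agree stimulus for stimulus. For a deterministic threshold \(T\) the
estimate always lies in \([T, T+2]\) — every counted success is at or above
\(T\), and the coarse ascent can overshoot by at most its own step — and is
monotone in \(T\).

## The subject simulator

The simulator generates the minimum structure the measurement relies on,
and no more:

* **Psychometric rule.** Each subject has a latent threshold \(T\); with
  slope 0 the response to intensity \(I\) is the deterministic step
  \(I \ge T\), otherwise Bernoulli with \(p = \mathrm{logit}^{-1}((I-T)/w)\).
  The deterministic step is the default: it is what the bracketing and
  recovery guarantees are stated for, and threshold "fuzziness" can be
  switched on explicitly where wanted.
* **EMG morphology.** Baseline activity is zero-mean Gaussian noise
  (default SD 0.01 mV, a typical quiescent surface-EMG level). A reflex
  adds a burst: a Gaussian envelope (SD 6 ms) centred at a jittered
  latency (mean 120 ms, SD 8 ms, clipped into the 90–150 ms window)
  carrying a 100 Hz oscillation phase-locked to the envelope centre. The
  envelope peak is `burst_gain` × baseline SD at threshold (default 20),
  growing linearly with the suprathreshold margin. Phase-locking the
  carrier makes the realised peak equal the programmed peak up to sampling
  and additive noise, which is exactly the contract the detector relies
  on: real reflex EMG is far richer (motor-unit interference patterns,
  habituation, crosstalk), and nothing downstream depends on morphology
  beyond the windowed peak. Simulated sweeps span −100 to +200 ms around
  onset at 2000 Hz, a typical surface-EMG acquisition rate.
* **Pain ratings.** A rounded, noisy logistic mapped onto the 0–10 scale:
  `round(10 * plogis((I - c)/w) + N(0, 1))`, clipped to [0, 10] — the
  simplest monotone ordinal model consistent with the scale's anchors. The
  value 4 ("liminal value for pain") is metadata for labelling, not
  simulation logic.

### Cohort defaults

`cohort_spec()` defaults describe the two-group study the measurement was
built for: 29 fibromyalgia (FM) subjects with latent thresholds
Normal(14.4, 6.4) mA and 21 healthy controls (HC) at Normal(14.7, 5.4) mA,
truncated to the operable 0.5–29.5 mA range (thresholds in both groups are
normally distributed with similar variance, and near-identical means — the
"negative result" structure the end-to-end null tests reproduce).
Covariate means and SDs (age, height, weight, blood pressure, current
pain, psychological distress, disability, perceived health) follow the
groups' clinical characteristics.

The rating-curve centres are expressed as offsets from the group threshold
mean: −8 mA (FM) and −4 mA (HC) with width 2.5 mA. These were calibrated
analytically against the staircase trajectory — the per-limb rating scalar
is the mean rating over *all* delivered stimuli, about half of which lie
below threshold during the coarse ascent — so that simulated cohorts land
near the ordinal rating medians of 7 (FM) vs 5 (HC). The lower FM offset
makes patients rate matched intensities as more painful throughout. A
Gaussian copula (`rating_threshold_rho`, default 0.5 in FM, 0 in HC) links
each subject's rating centre to their latent threshold, inducing the
positive threshold–rating association seen in patients without forcing it
in controls.

Dropout is per-limb Bernoulli with defaults 1/32 (FM, first limb), 5/32
(FM, second limb), 0 and 1/29 (HC) — a realistic attrition pattern that
exercises the analysis module's unequal-n handling, including the
single-limb fallback of the averaging rule.

### What the simulator does *not* model

No habituation or sensitization across stimuli (the jittered 8–12 s
inter-stimulus intervals are taken at face value), no stimulus artifact,
no electrode-impedance physics, no medication effects, no item-level
questionnaire structure. Passing tests therefore demonstrate the
correctness of the measurement logic and the statistical pipeline under
the stated generative model — not robustness to the full physiological
richness of patient EMG.

## Cohort statistics

Per-subject session summaries follow the bilateral averaging rule: when
both limbs were measured the subject's threshold (and rating) is the mean
of the two; with one limb, that limb's value. `analyze_cohort()` then
produces the study-shaped report: group summaries (mean, SD, t-based 95%
CI, median, IQR with interpolated quartiles), pooled two-sample t-tests
with Levene's homogeneity check alongside, normality diagnostics
(Shapiro–Wilk plus the |skewness| > 3 / |kurtosis| > 3 moment rules, SPSS
conventions), the Mann–Whitney comparison of ratings (exact enumeration
via the Gaussian-binomial null distribution when \(n_1+n_2 \le 20\) without
ties, tie- and continuity-corrected normal approximation otherwise, with
the method reported), paired t and Wilcoxon signed-rank limb comparisons
(zero differences dropped, Wilcoxon's original convention), per-subject
percent change between limbs, and Spearman correlations with Fisher-z
confidence intervals, \(\tanh(\operatorname{atanh}\rho \pm 1.96/\sqrt{n-3})\).

Two defaults worth stating: the pooled (Student) t is the default with
Welch behind a flag — the printed between-group p-values (e.g. age 0.49,
weight 0.02) back-compute under pooling, not Welch — and all tests are
two-sided at α = 0.05 with no multiple-testing correction, matching the
analysis the report tables summarise. `two_sample_t()` accepts either raw
samples or `(mean, sd, n)` summaries and gives identical results for
identical moments, which is what lets printed table rows be re-verified
without subject-level data.

## Reproducibility

Every session is driven by one integer seed; experiments derive
per-session seeds from a master seed through a documented 32-bit
multiplicative mix, and each session log records its seed, so any single
session can be replayed exactly from its log. Session logs are JSON under
a versioned schema (`nwr-session-1`, shipped in `inst/extdata/`); logged
stimulus sequences, not RNG bit-streams, are the portability contract.

## Problem sizes used in validation

The shipped tests and the acceptance script use: the full 296-point
deterministic threshold grid for staircase/oracle equivalence; 10,000
simulated sweeps each for the false-positive and burst-sensitivity rates;
200 subjects for closed-loop threshold recovery (reported against the
cohort's realised latent mean, since the staircase guarantee — bias in
[0, 2 mA] — is relative to each subject's actual latent threshold); 2,000
replicates for pooled-t type-I calibration at n = 29/21; and 150 full
detector-in-the-loop null experiments (identical generating distributions
in both groups) for end-to-end calibration, judged against a pre-computed
binomial band (rejection count 2–15 of 150 at the nominal 5% level).

## Known limitations

* The Z ≥ 12 criterion is defined on the raw windowed peak; if an
  acquisition chain rectifies or band-passes the EMG first, thresholds are
  not directly comparable (expose the `rectify` flag, or keep the chain's
  convention consistent).
* The simulator's burst model is intentionally minimal; it cannot be used
  to study detector behaviour under realistic artifacts (movement,
  stimulus bleed-through, mains hum).
* Percent-change summaries inherit the instability of ratios when
  first-limb thresholds are small; the analysis reports them as the plain
  per-subject mean, matching the summary-table convention, without
  robustification.
* The exact Mann–Whitney path requires tie-free data; integer pain
  ratings virtually always tie, so group rating comparisons use the
  corrected normal approximation in practice (the output says which path
  was taken).
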