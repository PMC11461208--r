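---
title: "Quantifying motor slowing from tapping sessions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor slowing from tapping sessions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measure

When a finger taps at maximal speed for 30 s, the tapping frequency drops
rapidly within the first seconds and then stabilises. This *motor slowing*
is an index of motor fatigability that is thought to reflect supraspinal
rather than muscular mechanisms, which makes it attractive as a simple,
scalable probe for clinical populations. tapfatigue quantifies it from raw
touchscreen recordings: each 30 s trial is reduced to six 5 s bin
frequencies, bins are averaged across the valid trials of a finger, and the
slowing of that finger is summarised as

- **maximal tapping speed** — the largest of the six bin means (Hz),
- **relative decrease** — `100 * (1 - min / max)` over the six bin means (%),
- **absolute decrease** — `max - min` (Hz).

The published equation for the relative decrease is typographically
garbled (it reads as a min/max ratio). We implement the *decrease* reading,
because the quantity is described as a ~17% decrease, which is consistent
with `min/max` being about 0.83 rather than 0.17. The ratio variant remains
available via `compute_decreases(..., variant = "ratio")` for audit.

## Pipeline

1. **Ingest** (`read_session()`, `assign_fingers()`, `detect_taps()`).
   Sessions are directories of plain CSV: a participant file, an 18-trial
   schedule, a 50 Hz touch-event stream (`began`/`moved`/`ended` phases per
   pointer), and a device accelerometer stream. Touch contacts are labelled
   index/middle/ring/little from their x-coordinates: home positions are
   established from the initial resting placement ranked by x (ascending
   for a right hand, mirrored for a left hand) and every later contact is
   claimed by the nearest home. A tap is a `began` event (touch-down) of
   the instructed finger inside the half-open window `[cue, tap_end)`;
   inter-tap intervals (ITIs) are its successive differences. A touch by
   any other finger counts as a *wrong-finger tap* only if its contact is
   transient (≤ 1 s); long contacts are resting placements. This duration
   rule is our operationalisation wherever "tapping" must be distinguished
   from re-placing a resting finger — the protocol itself does not define
   the distinction.

2. **Quality control** (`evaluate_session()`). Seven criteria, in order:
   (1) device motion — any 0.25 s moving-average accelerometer sample
   (13 frames at 50 Hz, edges truncated) beyond 0.03/0.045/0.4 device units
   in |x|/|y|/|z| during tapping; (2) start latency > 1.5 s after the cue
   (a trial with no taps also fails here, so empty trials fail
   deterministically); (3) any wrong-finger tap, or < 3 fingers on the
   screen for > 3 s cumulative; (4) the maximal bin frequency not attained
   in the first 10 s (bins 1–2); (5) the minimal bin frequency not attained
   in the last 10 s (bins 5–6); (6) tapping during the rest period, or
   (after a 5 s grace) < 4 resting fingers for > 3.5 s cumulative;
   (7) ITIs > 2 s are removed as missing data, with at most 3 removals and
   no gap > 5 s. Criteria 4–5 operate on the binned frequencies of the
   criterion-7-cleaned series, which makes the 10 s windows exact; ties
   (e.g. a flat curve) pass, because *some* bin attaining the extremum lies
   in the required range. A multiply-failing trial is attributed to its
   lowest-numbered failing criterion; attribution is therefore a partition
   and per-criterion percentages sum to the total exclusion rate. The
   finger-count allowances are accumulated cumulatively over the window
   (the conservative reading of "allowed for maximally 3 s"). Missing
   accelerometer data warns and passes by default (`missing_accel`
   config). The cascade drops a finger when **more than 3** of its 6 trials
   are excluded (a finger with exactly 3 exclusions is retained) and drops
   a participant when all three fingers are dropped.

3. **Features** (`bin_trial()`, `compute_features()`). The bin frequency is
   a fractional tap count over the effective covered duration: each
   retained ITI contributes `overlap/ITI` taps and `overlap` seconds to
   every bin it spans. Removed ITIs and the spans before the first and
   after the last tap contribute nothing. This is count-per-effective-time
   made exact at bin edges: a whole-trial 5 Hz tapper yields exactly
   `[5,5,5,5,5,5]`, a removed 2.5 s dropout leaves its bin's frequency
   unchanged (the denominator shrinks with the numerator), and a bin with
   no coverage has frequency 0. Conservation holds in interval form:
   `sum(bin_freq * coverage)` equals the number of retained ITIs. Max/min
   are taken on the trial-averaged curve, not per trial: averaging first is
   the stated order of the original analysis, and per-trial extremes would
   be upward-biased under noise.

4. **Statistics** (`fit_lmm()`). Three feature models (maximal speed,
   relative decrease, absolute decrease) regress their response on
   `AgeGroup * Finger + Sex + Sex:Finger` with a participant random
   intercept; the time-course model regresses the binned frequency on
   `Time * Finger * AgeGroup + Sex + Sex:Finger`, `Time` a 6-level factor.
   Fits are REML (lme4); type-III F tests use Satterthwaite denominator
   degrees of freedom (lmerTest) under sum-to-zero contrasts, which
   type-III marginality requires. Effect sizes are partial eta squared,
   `F*df1/(F*df1 + df2)`. Before each fit, observations whose standardized
   residual from an MM-type robust regression of the fixed-effect design
   exceeds 2.5 in absolute value are removed (MASS::rlm; per-cell
   median/MAD fallback; cells with < 3 observations are protected). The
   cutoff is configuration, and every removal is logged with its residual.
   The post-hoc family is the six contrasts implied by the age-by-finger
   interaction — the young−aged difference within each finger and the three
   pairwise differences of those differences — tested as asymptotic z
   statistics with the single-step max-|z| multivariate-normal adjustment
   (Bonferroni fallback); adjusted p values are never below the raw ones.

## The synthetic generator

Because raw participant data cannot ship with a package, every stage is
exercised against `generate_cohort()`, which emulates the study protocol
exactly: 18 trials in 6 blocks, each finger once per block in randomised
order, 30 s tapping + 30 s rest, with the rest extended by 30 s after
blocks 2 and 4. Non-tapping, non-thumb fingers rest on the screen
continuously; the tapping finger lifts shortly before its cue and re-places
shortly after its trial ends. Accelerometer noise is white with standard
deviations at most a quarter of each motion threshold after smoothing.
Every session carries its generative ground truth (profile parameters and
injected violations), so tests can score quality-control decisions against
labels rather than heuristics.

**Within-trial speed profile.** `slowing_profile()` holds the initial rate
`f0` over the first 5 s, declines along a saturating-exponential ramp
(time constant `tau`, default 30 s, i.e. a gently concave, near-linear
drop), and settles on a floor of `f0*(1-decrease)` from 22.5 s. The
hold–ramp–floor shape was chosen deliberately: the time averages of the
first and last 5 s bins then equal `f0` and `f0*(1-decrease)` *exactly*, so
the generative `decrease` parameter coincides with the binned
relative-decrease estimand. For any strictly decreasing curve the binned
estimate is necessarily smaller than the endpoint decrease (the first bin
averages below `f0`, the last above the endpoint) — by 2.6–4.4 percentage
points at a 17% decrease for exponential-family curves — which would make
"the pipeline recovers the generative decrease" ill-posed. Anchoring the
estimand at the bins makes parameter recovery a meaningful test; it is a
statement about how the parameter is *defined*, not a claim about curve
shape in real tappers.

**ITI jitter and quality-check margins.** ITIs are multiplicative
log-normal (strictly positive) with coefficient of variation `iti_cv`,
default 0.02, and cohort `decrease` values are sampled within
[0.12, 0.28]. These defaults are narrower than human tapping variability,
and that is intentional: the speed-profile criteria 4–5 are argmax/argmin
rules on six noisy bin frequencies, and with realistic jitter (CV ≈ 0.1)
they misfire on several percent of perfectly honest trials — which is
exactly why the original study excluded 13.3% and 17.6% of real trials on
these criteria. The generator's *clean* trials are instead meant to be
unambiguously clean (≥ 4σ margins on every criterion), so that any
exclusion of a nominally clean synthetic trial marks a pipeline defect,
not bad luck. Group means of the sampled decrease (17.0% young, 16.5%
aged) are prioritised over the between-participant spread for the same
reason. Consequences for interpretation: passing the clean-pass and
confusion-matrix tests shows the decision logic is correct, *not* that
real-data exclusion rates will be low; the generator does not emulate
learning or warm-up effects, tremor, palm touches, device-specific
accelerometer units, or the heavy tails of real ITI distributions.

**Violation injections.** `inject_violation()` corrupts a trial so that it
unambiguously fails one requested criterion and, at the default magnitudes
(≥ 1.5× each threshold), no other: a 2 s constant-offset accelerometer
block (criterion 1), dropped early taps (2), brief wrong-finger taps (3),
re-synthesised tap series whose frequency peaks after 10 s (4) or dips
before the last 10 s (5), transient touches during rest (6), and single
long or repeated short tap gaps (7). Magnitudes that are not strictly
beyond their threshold are rejected at construction.

## Numerical details and degenerate inputs

Touch events are snapped to the 50 Hz frame grid; the final tap of a trial
is kept strictly inside the half-open tap window so snapping cannot leak a
tap into the rest period. Times are stored at 2 decimals, coordinates at 4,
accelerations at 5, so sessions round-trip bit-exactly through CSV. The
moving average truncates its window at the series edges rather than
padding. Zero-tap trials fail the latency criterion; `compute_decreases()`
flags a zero maximal speed instead of dividing by zero; an empty cohort
yields an all-zero exclusion report. `run_pipeline()` orders participants
canonically by id so the outputs are identical whether the cohort was
generated in memory or re-read from disk, and its manifest records an MD5
hash per output file.

## Problem sizes used by the test suite

The packaged checks run a 60-participant cohort with mixed injections for
the quality-control confusion matrix, 100 trials per decrease setting
(5%, 17%, 30%) for parameter recovery at `iti_cv = 0.01`, 200 null
replicates (n = 60 participants) for the type-I error of the age-group F
test with the full outlier-removal-plus-REML stack, and 100 replicates for
interaction recovery. These sizes keep the whole suite under a few minutes
while leaving the Monte-Carlo acceptance bands (e.g. type-I error in
[0.02, 0.09]) comfortably wide relative to binomial noise.

## Known limitations

- The effect-size arithmetic `F*df1/(F*df1+df2)` reproduces seven of the
  published effect sizes at their printed precision; two printed values
  (0.32 for the Finger effect in the absolute/relative-decrease analyses
  and 0.04 for Time × Finger) are not consistent with their own printed F
  and degrees of freedom under this formula (they give ≈ 0.29 and
  ≈ 0.005), and one (0.004 for Sex × Finger) rounds to 0.005. We document
  rather than resolve this.
- Whether the original preprocessing attributed multiply-failing trials to
  one criterion or counted them under all, and whether the finger-count
  allowances are consecutive or cumulative, is not specified; we use
  first-fail attribution and cumulative allowances.
- Whether taps were timestamped at touch-down or touch-up is not stated;
  we use touch-down, matching what an on-screen tap counter displays.
- Accelerometer thresholds are in unstated device units; the generator
  simply respects the thresholds' ratios.
- The deposited dataset's native layout is undocumented here; an adapter
  would map it onto the session-directory format, and cohort-level counts
  (participants excluded, valid fingers) could then be compared directly.
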