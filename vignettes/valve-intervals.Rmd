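---
title: "Fetal valve intervals and gestational age: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fetal valve intervals and gestational age: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what the synthetic evaluation does and does
not demonstrate.

## The measurement model

A 1-D Doppler ultrasound (DUS) transducer aimed at the fetal heart returns
an audio signal whose ~200 Hz component is dominated by valve-leaflet
motion.  Four bursts per cardiac cycle correspond to mitral closing (Mc),
aortic opening (Ao), aortic closing (Ac) and mitral opening (Mo); extra
transitional bursts (T1–T4) appear between them and carry no valve
information.  A simultaneously recorded, already-extracted fetal ECG
supplies the R peaks (cycle anchors) and the Q onset needed for the
electromechanical delay time.  The seven intervals EDT, ICT, VET, IRT,
VFT, PEP and STI follow by subtraction; PEP and STI are linear
combinations of the others and are therefore never used as regression
inputs.

Gestational age is estimated by polynomial regression on record-level
interval medians.  The shipped valve model (coefficients −276.810, 5.496,
7.897, 0.682, −0.140, −0.017 over the terms 1, EDT, ICT, VFT, EDT·ICT,
ICT·VFT; residual SD 4.01 wk) and the shipped FHRV model (4.788 +
0.064·mRR + 0.120·SDRR; residual SD 5.55 wk) are stored at their printed
three-decimal precision, so any prediction inherits that rounding.  A
consequence worth knowing: reconstructing a t-statistic as estimate/SE
from rounded tables can deviate from the printed t by more than a fixed
0.05 when the SE itself is small — `published_model_self_check()` reports
both the fixed-tolerance comparison and the half-ulp rounding bound, and
the package treats consistency *at printed precision* as the meaningful
check.

## Stage-by-stage choices

**R peaks.**  Band-pass 5–45 Hz, derivative, squaring, 80 ms integration,
adaptive threshold with a 200 ms refractory period; peak times refined to
the local maximum of the band-passed magnitude.  RR intervals outside
250–1100 ms (FHR ≈ 55–240 bpm) are rejected.

**Q onset.**  Within 60 ms before each R, the first sustained (≥ 3 ms)
excursion of the low-passed derivative above 5% of the R upstroke slope
marks the deflection; the onset is then refined by the tangent method —
the early-ramp tangent (2 ms past the crossing) extrapolated back to the
local baseline, with the 3 ms next to the crossing excluded from the
baseline because the zero-phase filter smears the ramp backwards into
them.  The tangent construction cancels the symmetric filter smear, which
otherwise biases EDT by ≈ 1 ms — material, since ∂GA/∂EDT can reach
≈ 2 wk/ms at low ICT.  Undetectable onsets fall back to a flagged fixed
20 ms.

**bSQI.**  Agreement of the Pan-Tompkins style detector with a
deliberately fragile amplitude-threshold detector: greedy one-to-one
matching within 50 ms, score `N_m / (N_a + N_b − N_m)`.  Empty detections
on both sides score 0.

**Valve band.**  Continuous wavelet transform with the second-order
complex Gaussian wavelet at the single scale whose centre frequency is
closest to 200 Hz (selection by centre frequency, not by a literal scale
index, which is implementation-dependent).  The discrete kernel at this
short scale retains ≈ 8% negative-frequency energy, so its two-sided
magnitude ripples at twice the carrier rate; the envelope chain (below)
expects exactly that.  A one-sided ("analytic") variant of the same
transform is computed alongside: its magnitude is a smooth demodulated
envelope whose peaks sit at the burst centres to sub-sample accuracy, and
it serves two purposes — sub-sample refinement of decoded event phases
(parabolic interpolation around the local maximum), and a second source of
peak candidates, because the 30 Hz-smoothed envelope cannot resolve
Mc–Ao doublets closer than ≈ 25 ms, which short isovolumic contraction
times do produce.

**Envelope and segmentation.**  Absolute value, cubic spline through its
local maxima, zero-phase low-pass at 30 Hz, clipped at zero.  Segments run
from each R peak to one sample before the next, are z-normalised, and are
dropped (logged) when the RR is implausible or the envelope is constant —
a zero-variance segment carries no valve information and would corrupt
clustering.

**DUS quality.**  Twelve per-segment indices against the plausible valve
windows Mc 9–44, Ao 45–90, Ac 200–260, Mo 265–326 ms after the R peak:
four inside/outside ratios (power, peak count, mean peak amplitude,
variance) mapped r → r/(1+r) to bound them; kurtosis; skewness; Hjorth
complexity (one scalar had to be chosen for the "Hjorth parameters" slot —
complexity is the most morphology-sensitive, and mobility stays available
as a diagnostic); four sample entropies with (m, r) = (1, 0.1), (1, 0.2),
(2, 0.1), (2, 0.2), r scaled by the segment SD; and the minimum over
window sizes 10, 15, …, 100 of the 2nd/1st singular-value ratio of the
stacked non-overlapping-window matrix (0 for an exactly periodic segment
whenever a window divides the period; the trailing partial window is
discarded).  Features are min-max normalised with bounds stored at
training time (corpus-wide, kept with the model) and clipped at
inference; a kernel-density Naive Bayes classifier (per-class, per-feature
Gaussian KDE with Silverman bandwidth; priors from label frequencies)
yields a per-segment posterior, and the record score is the mean
posterior — the aggregation had to be chosen, and the mean keeps the score
sensitive to the fraction of bad segments.

**Event decoding.**  Segments are linearly resampled to 512 samples and
K-means clustered into six morphologies (10 restarts, best
within-cluster SS, ties in assignment broken toward the lowest index).
Per cluster, a multiclass SVM with probability calibration over
(phase ms, phase fraction of the cycle, amplitude) emits label
probabilities for the eight events; phase fraction is included because
FHR spans 60–210 bpm and absolute phases stretch with the cycle.
Transitions are add-one-smoothed label bigrams.  Decoding is a Viterbi
search over the joint state (label, set of valve labels used), enforcing
that each valve fires at most once per beat — anatomy implies it, and the
constraint is what makes the exact dynamic program worthwhile.  The
brute-force path enumerator stays in the package as the reference
implementation and the test suite requires exact agreement on every
segment with ≤ 6 candidates.  A cyclic label order is *not* enforced:
only the one-use constraint is, since transitional peaks can appear
anywhere in the cycle.  Clusters with fewer than 30 labelled training
beats fall back, flagged, to a pooled model.

**Intervals.**  VFT ends at the *next beat's* mitral closing — diastolic
filling ends when the mitral valve shuts; with phase-locked synthetic
beats this makes ICT+VET+IRT+VFT equal each RR exactly, which the tests
assert as an identity.  Records aggregate by median (and median absolute
deviation) over quality-accepted beats: robust to residual decode errors
in one-minute records, where a mean would not be.

**FHRV.**  mRR, SDRR (n−1 denominator), RMSSD; spectral analysis on the
tachogram linearly resampled at 4 Hz (comfortably resolving the 1 Hz HF
edge), mean removed, single Hann-tapered periodogram, band powers
integrated over LF 0.03–0.15, MF 0.15–0.5, HF 0.5–1 Hz.  Total power is
defined as the integral over the union 0.03–1 Hz, so LF+MF+HF = TP up to
integration tolerance, and LF/(MF+HF) is undefined (NA) when the
denominator is numerically zero.

**Regression.**  Candidate pool: forced intercept plus all linear,
squared and pairwise-product terms of the supplied predictors, with no
hierarchy constraint (the shipped model itself contains products without
squares).  Forward entry at partial-F p < 0.05; backward removal at
p > 0.10 — the removal threshold is a package choice (only entry is
pinned by the procedure's definition) and is exposed as an argument.  A
term never re-enters immediately after removal, so selection terminates.
Leave-one-out CV re-runs the *entire* selection per fold; fold-to-fold
term sets legitimately differ when the signal is weak.  Partial
correlations use the residual method (regress both variables on the
controls, correlate residuals, t-test on n−2−k df).

## The simulator: what it emulates, what it does not

`synth_params()` defaults define the evaluation conditions: 1-minute
records at 1 kHz; GA between 16 and 41 weeks; mean FHR falling linearly
160 → 140 bpm over 16 → 41 weeks (consistent with a positive mRR
coefficient in the FHRV model); per-beat RR jitter Gaussian with SD 2.5%
of the mean RR (enough for nonzero SDRR/RMSSD without dominating the
spectrum); valve bursts as 24 ms Hann-windowed 200 Hz cosines with
amplitudes Mc 1.0, Ao 1.2, Ac 1.1, Mo 0.9 and transitional 0.4 (extra
transitional burst with probability 0.3 per beat); QRS as a 30 ms
piecewise-linear biphasic template whose deflection starts exactly at the
Q onset, 12 ms before R — no fetal Q-to-R offset is established in the
literature we model, and 12 ms keeps Mc phases (EDT − offset) inside the
plausible 9–44 ms window given EDT ∈ (20, 45) ms.  Both channels are
rendered by evaluating the continuous templates at the sample times
rather than snapping to the grid: snapping introduces a constant
per-record quantisation offset of up to ±1 ms between the fECG and DUS
channels that medians cannot remove, and that error floor is what the
decoder's sub-millisecond refinement would otherwise inherit.

In `model_inverse` mode the intervals are drawn uniformly (EDT 20–45,
ICT 25–45, VFT 120–250 ms — chosen so the polynomial stays in a plausible
range; no fetal interval distributions are established to draw from) and
GA is the shipped polynomial plus Gaussian noise (default SD 4.01 wk),
clipped to [16, 41].  One caveat discovered numerically: over the full
uniform box the polynomial itself spans roughly −8 to +73 weeks, so the
clipping censors ≈ 20% of records.  Censoring the response biases any
refit (the EDT slope recovers near 3.6 instead of 5.5), so `clip_ga =
FALSE` must be used — and is, in the acceptance script and recovery
tests — whenever the cohort feeds coefficient recovery rather than
pipeline evaluation.  `uniform_ga` mode instead draws GA uniformly and
makes the intervals affine in GA plus noise.

What the simulator does **not** emulate: maternal ECG residue and fECG
extraction artefacts, movement and transducer-repositioning noise,
beat-to-beat interval variability (event phases are phase-locked within a
record), multi-gate Doppler effects, or realistic PQRST morphology.
Passing the synthetic suite therefore demonstrates algorithmic
correctness — exact decoding, unbiased timing, correct arithmetic and
selection behaviour — not clinical performance on recorded data.  The
cohort-level numbers of any real study (MAE in weeks, retained-record
counts, error–GA correlations) depend on a recorded corpus this package
does not ship and makes no claim to reproduce; the abnormal-case table
bundled in `inst/extdata/` is a fixed reference for arithmetic and
flagging checks (estimates above 42 weeks mark records where the
condition breaks the regression's assumptions), not a benchmark.

## Numerical details and degenerate inputs

Sub-sample positions (event phases, Q onsets) use parabolic or tangent
interpolation; ties in K-means assignment go to the lowest index; Viterbi
ties resolve to the first-enumerated optimum, and the brute-force oracle
agrees because both maximise the identical score.  Sample entropy guards
empty template counts with an epsilon, returning a large finite value for
perfectly regular segments.  Ratio features with a zero denominator map
to 1 (all energy inside the valve windows) and are flagged.  Constant
normalisation columns map to 0.5.  Records failing any stage propagate as
a row of NAs with a reason string, never as an error.

Test problem sizes are deliberately desk-scale: training corpora of five
20-second records, evaluation cohorts of 20 records of 35 s, a 5000-record
tabular cohort for coefficient recovery, and ≥ 500 segments for the
decoder-exactness check.  These sizes were chosen to exercise every code
path with stable statistics; all of them are parameters, not limits.

## Known limitations

Q-onset estimation assumes a resolvable Q deflection; monophasic spikes
fall back to a fixed offset.  The envelope chain trades temporal
resolution for stability — without the analytic-track candidates it
cannot separate Mc from Ao below ≈ 25 ms of ICT.  The quality classifier
is only as good as its training labels; the shipped training helper
labels by construction (clean vs. heavily corrupted renders), which is a
coarser notion of quality than human annotation.  Stepwise selection
inherits the usual instabilities of F-test-driven selection near the
threshold; the leave-one-out layer reports, rather than hides, the
fold-to-fold term variation.
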