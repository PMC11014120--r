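---
title: "Methods: gyroscope-based segmentation of the Placing Bricks test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gyroscope-based segmentation of the Placing Bricks test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placingbricks)
```

## The measurement problem

The Placing Bricks (PB) test is a timed fine-motor task: a child moves 18
toy bricks, one at a time, from a pile onto a board as fast as possible.
The standard score is a single number, the total completion time. A wrist
gyroscope turns the same minute of movement into a rich signal from which
every movement cycle can be decomposed into four phases:

* **Grasping** — from first contact with a brick (*Initial Grasping*, IG)
  to lifting it off the pile (*Grasping End*, GE);
* **bricks-to-board flight** — hand transport to the board (GE to
  *Initial Placing*, IP);
* **Placing** — fitting the brick onto the board (IP to *Placing End*,
  PE);
* **board-to-bricks flight** — the empty-handed return (PE to the next
  IG).

A *cycle* runs from one IP to the next; a complete 18-brick trial contains
exactly 17 full cycles. This package implements the full chain: signal
ingestion, filtering, event detection, cycle segmentation, variability
metrics, validation against reference annotations, nonparametric group
comparison, and a synthetic-trial generator with exact ground truth.

## Signal model and preprocessing

The detection variable is the *target signal*: the algebraic sum of the
angular velocities about the wrist's longitudinal (L) and antero-posterior
(AP) axes. A sum — rather than a norm — keeps the sign, and the sign is
informative: flights toward the board produce positive peaks, returns
produce negative ones. The medio-lateral axis carries little
task-related rotation and is not used.

The target is low-pass filtered with a 4th-order Butterworth design at
6 Hz, applied forward and backward. Zero-phase filtering matters because a
causal filter would delay every event estimate by tens of milliseconds —
a systematic bias of the same order as the effects being measured. The
implementation details are fixed for reproducibility:

* the digital filter comes from the bilinear transform with cut-off
  prewarping (`signal::butter`), so the forward–backward magnitude
  response is exactly
  $|H(f)|^2 = \left(1 + \left(\tan(\pi f/f_s)/\tan(\pi f_c/f_s)\right)^{8}\right)^{-1}$,
  which equals the continuous-time Butterworth expression
  $(1 + (f/f_c)^{8})^{-1}$ in the passband and at the cut-off (gain
  exactly 1/2 at 6 Hz) but deviates from it far above the cut-off because
  of frequency warping;
* edges are handled by odd (point-symmetric) reflection padding of
  `3 * order` samples with steady-state initial conditions, so a constant
  signal passes through bit-exactly (unit DC gain) and no spurious edge
  transients leak into the first and last seconds.

Which wrist wore the sensor flips the raw sign of the signal. Orientation
is decided from the data by a timing asymmetry of the task itself: the gap
following a true positive (toward-board) peak contains the Placing phase,
the longest contact phase, while the gap after a negative peak contains
the much shorter Grasping phase. The signal is negated when the median gap
after positive peaks is the shorter one. The gap statistics are computed
on the same alternation-pruned peak set used by the detector, so secondary
same-sign peaks (e.g. placement adjustments) cannot bias the decision.

## Event detection

Detection proceeds in two stages.

**Flight peaks.** Local extrema of the filtered target whose absolute
amplitude exceeds a prominence threshold — a fixed fraction (0.2) of the
90th percentile of the absolute signal — are kept, with same-sign peaks
closer than 0.3 s pruned to the larger one, and sign alternation enforced.
All thresholds are relative to the trial's own amplitude scale, so
detection is invariant to sensor gain and units.

**Events from valleys.** Each task event is a near-stationary instant of
the wrist between two movements, i.e. a local minimum of the *absolute*
signal. For each positive peak, the nearest qualifying minimum before it
is GE and after it is IP; for each negative peak, PE before and IG after.
A minimum qualifies when it falls below half the adjacent peak's absolute
amplitude; if no local minimum in the valley qualifies, the valley's
global minimum is used. Finally the sequence is trimmed to the task
proper, from the first IG to the last PE, which removes the events
generated by the initial reach from rest to the pile and the final return
to rest.

The event grammar IG → GE → IP → PE → IG … is checked, never silently
repaired: violations are reported as warnings (or errors in strict mode),
and segmentation drops any cycle containing a break rather than
extrapolating through it.

## Segmentation and variability metrics

Cycles are anchored at IP (the event kind located most reliably, since
Placing is bracketed by the two largest, cleanest peaks). Within a cycle
the four phase durations are read directly off the intervening events and
therefore sum to the cycle duration exactly — an identity the tests
assert at machine precision.

Per-trial variability uses median, interquartile range, range and the
Poincaré (lag-1 return map) indices

$$SD1 = \sqrt{\tfrac{1}{2}\,\mathrm{Var}(x_{i+1}-x_i)}, \qquad
  SD2 = \sqrt{\max\!\big(0,\; 2\,\mathrm{Var}(x) - SD1^2\big)},$$

with sample (n−1) variances throughout — with only 17 cycles per trial
the denominator convention is material, so it is pinned down. Two
numerical caveats are handled explicitly rather than left to produce
`NaN`s: for strongly alternating short series $2\mathrm{Var}(x) - SD1^2$
can be negative (clamped to zero and flagged `sd2_clamped`), and for
$n = 2$ both indices are undefined (`NA`).

A finite-sample subtlety worth recording: $SD1$ equals the standard
deviation of the Poincaré cloud's projection perpendicular to the
identity line *exactly*, but the $SD2$ formula above equals the
along-identity projection SD only asymptotically. For $x = 1,\dots,5$
the formula gives $\sqrt{5} \approx 2.236$ while the cloud projection
gives $1.826$. The formula is the conventional definition and is what
this package computes; the equivalence test against the cloud oracle in
`test-acceptance.R` is therefore expected to fail for $SD2$ and is kept
as an honest record of that finite-n divergence.

## Validation against reference annotations

A detected event counts as a correct identification of a reference event
at time $r$ with neighbours $p$ and $f$ (of any kind) when it falls in
$[(p+r)/2,\,(r+f)/2]$ — the second half of the preceding phase or the
first half of the following one. Boundary events use the recording start
and end as missing neighbours. Matching is per kind, one-to-one, greedy
by smallest absolute time difference, making the assignment deterministic
and order-independent. Sensitivity is the percentage of reference events
matched; positive predictive value is the percentage of detections that
match.

Agreement of paired duration measurements uses Bland–Altman statistics
(mean difference and 95% limits of agreement, $\pm 1.96\,SD$ of the
differences) plus the Pearson correlation. A phase duration passes the
reliability gate when all three hold strictly: $|md| < 0.1$ s, the full
width of the limits of agreement below 50% of the median duration, and
$\rho > 0.9$. The *full* width convention (i.e. $2 \times 1.96\,SD$
relative to the median) is deliberate; the acceptance tests verify that
it reproduces the published reliable/unreliable classification of the
five duration measures from reported summary statistics.

## Group statistics

Phase durations are right-skewed, so the analysis pipeline is
nonparametric throughout: Mann–Whitney U for independent factors (sex,
age group) and Wilcoxon signed-rank for hand dominance (paired within
participant). Rather than relying on `stats::wilcox.test`, which refuses
exact p-values under ties, small samples are handled by direct
enumeration — all $\binom{n_x+n_y}{n_x}$ group assignments for combined
sizes up to 20, and all $2^n$ sign patterns for up to 15 non-zero paired
differences — which stays exact in the presence of ties. Larger samples
use the normal approximation with tie and continuity corrections. A
Kolmogorov–Smirnov screen against a fitted normal is provided for
reporting; it never gates the pipeline (and is conservative, since the
normal parameters are estimated from the same data).

## The synthetic generator

The generator produces trials with exact ground truth, and is the basis
of every end-to-end test:

* per-cycle phase durations are lognormal, parameterised by median and
  log-scale dispersion (defaults: Grasping 0.25 s, toward-board flight
  0.45 s, Placing 0.74 s, return flight 0.37 s), rounded to the sampling
  grid;
* each flight is a squared-sine velocity bell spanning its phase —
  zero value *and slope* at both ends, a minimum-jerk-like profile. This
  choice is load-bearing: a half-sine (discontinuous slope at the ends)
  is visibly widened by the 6 Hz filter, displacing the valley minima by
  several samples and biasing every contact-phase duration;
* contact phases carry low-amplitude 9 Hz tremor-band wiggle (above the
  filter cut-off), tapered by a sine window so the phase boundaries are
  the stationary instants of the contact — without the taper, tremor
  troughs occasionally displace the detected valley minimum by up to
  ~0.1 s;
* the trial is framed by rest, an initial reach to the pile (a negative
  pulse ending at the first IG) and a final return to rest after the last
  PE, as in the task protocol — necessary for the first IG and last PE
  to exist as detectable valleys;
* the target is split between the L and AP axes with a random per-trial
  mixing ratio (their sum reconstructs it exactly, so ground truth is
  independent of the split), white measurement noise is added per axis,
  and a left-wrist trial negates L and AP.

Ground-truth times sit on the cumulative sample grid, so the generator's
time convention and the detector's (sample $i$ at $(i-1)/f_s$) can differ
by a fixed one-sample offset; tests allow ±2 samples. With tremor
disabled, noise-free detection recovers every event within that bound;
with default tremor, a small tail of GE events lands up to ~7 samples
early (the absolute-signal minimum genuinely sits where the flight
pulse's filtered tail meets the rising tremor envelope, not at the
nominal boundary), which is the physical accuracy limit of the
valley-minimum definition rather than an implementation artefact.

A cohort generator layers group effects on top — multiplicative shifts
of the medians and dispersions for the younger age group and the
non-dominant hand, a per-child lognormal speed factor, and derived
per-trial seeds so the whole cohort is reproducible from one master seed.

### Realism and limits

The simulator reproduces the timing structure, signed-peak geometry,
amplitude scale and noise floor of the real task, which is what the
detection and segmentation layers consume. It does not model: drift or
bias in the gyroscope, brief hesitations or aborted reaches (beyond the
optional placement-adjustment pulses), cross-axis leakage that varies
within a trial, or tremor whose amplitude is largest mid-phase rather
than zero at phase boundaries. Consequently, detection accuracy on
synthetic data is an upper bound, not an estimate, of real-world
accuracy.

## Problem sizes and runtime

A trial is roughly 36 s × 128 Hz ≈ 4 600 samples; the full pipeline on
one trial runs in ~40 ms. The complete test suite (including 100
simulated trials for the fidelity and recovery criteria and 4 000
null replicates for statistical calibration) runs in well under a
minute.

## Limitations

* The valley-minimum definition bounds localisation accuracy by the
  interplay of filter leakage and near-boundary movement; see above.
* The reliability gate and matching rule encode one specific published
  convention each; both are pinned by tests but other conventions exist.
* Exact enumeration branches are $O\!\big(\binom{n}{n_x}\big)$ and
  $O(2^n)$ and are therefore capped (20 combined / 15 pairs); beyond the
  caps the usual approximations apply.
* The KS normality screen is conservative (estimated parameters); it is
  reported, never used as a gate.
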