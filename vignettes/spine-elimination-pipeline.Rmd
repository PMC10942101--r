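---
title: "Functional predictors of dendritic spine elimination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional predictors of dendritic spine elimination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinefate)
```

# The scientific problem

During motor learning, a fraction of dendritic spines on cortical pyramidal
neurons is eliminated. `spinefate` implements an analysis pipeline that asks
which structural and functional features of a spine predict its elimination,
working from two kinds of raw time series recorded during a cued lever-press
task:

* a lever displacement trace (~1--10 kHz) with trial event times (cue onset,
  reward), and
* per-ROI fluorescence time series (~58.3 Hz, acquired in 5-min-on /
  5-min-off blocks) for spine glutamate sensors (iGluSnFR2/3) and dendritic
  calcium (RCaMP2), with per-spine metadata: dendrite membership, position
  along the dendrite in micrometers, per-session presence, and areas.

The pipeline's endpoint is a set of stable-versus-eliminated comparisons:
event rates and task tuning, short-range co-activity (functional
clustering), the co-activity environment around each eliminated spine, and
the relative onset timing of spine events with respect to dendritic calcium
events (a proxy for postsynaptic spiking via back-propagating action
potentials).

Because the raw imaging data behind these analyses are not publicly
deposited, the package ships a first-class synthetic-session generator with
full ground truth. Every stage is tested against that ground truth or
against independent brute-force oracles.

# Processing model, stage by stage

## Movement segmentation

Lever traces are down-sampled to 1 kHz (decimation after anti-alias
filtering), smoothed with a zero-phase four-pole 10-Hz low-pass Butterworth
filter, and differentiated; the velocity is smoothed with a 5-ms moving
average and its envelope taken via the Hilbert transform (analytic-signal
magnitude). Tentative bouts are runs where the envelope exceeds 4.9 mm/s,
extended by 75 ms on each side; bouts separated by less than 500 ms are
merged (the extension is applied before the merge). Start and end times are
then refined against a displacement threshold: the local resting position
(median of rest windows flanking the bout) plus the 99th percentile of the
smoothing residual (raw minus Butterworth-smoothed trace).

Decisions where the procedure is under-specified:

* The rest periods used for the local resting position default to 500 ms
  windows flanking the scanned region (configurable via `rest_window_s`).
  The refinement scan starts one rest window before the tentative bout so a
  slowly rising press can be assigned an earlier, displacement-defined
  onset.
* Crossings are read off the *smoothed* trace. The threshold is defined
  from the smoothing residual, which the smoothed trace clears only during
  genuine movement; reading crossings off the raw trace would trigger on
  single noise samples at the 1% rate the percentile implies.
* The filter is applied forward-backward (zero phase) so refined bout times
  are not delayed by filter lag.
* A bout is `rewarded` when a reward time falls inside it, and `cued` when
  it starts during its trial's cue period, which lasts at most 10 s and
  closes at the reward.

Movement windows for kinematic comparisons are fixed at 0.5 s before to
1.5 s after onset; movements longer than 3 s, and movements whose windows
overlap another movement's window, are excluded. The learned movement
pattern (LMP) is the average rewarded, cue-initiated trajectory of the late
training sessions; stereotypy is the mean pairwise Pearson correlation
among a spine's coincident movements.

## dF/F0 and event detection

The time-varying baseline F0 is estimated per acquisition block by
iteratively smoothing the inactive portion of the raw trace: mask frames
whose provisional dF/F0 (0.5-s smoothed) exceeds twice the provisional
noise, re-smooth the unmasked trace with a long window (default 30 s),
repeat until the mask is stable (at most 10 iterations). If nearly all
frames end up masked the estimate falls back to a running 10th-percentile
baseline with a warning. dF/F0 = (raw - F0)/F0 is then denoised with a
0.5-s moving-average window.

Noise is the population SD of the negative dF/F0 values mirrored about the
origin, i.e. `sqrt(mean(neg^2))`: the mirrored multiset is a constructed
population with zero mean, so the population (not sample) SD is the
natural choice and is fixed throughout.

Events are active portions where a 1-s LOESS-style smoothed dF/F0 exceeds
2x the noise (3x for dendritic calcium). The smoother is a local linear
regression with tricube weights over a 1-s span; with symmetric weights the
fitted value at the center equals the tricube-weighted mean, so the whole
series is computed as one convolution (edges by reflection). Each active
portion is extended backward from its raw peak along the *unsmoothed* trace
to the most recent 1x-noise crossing, and ends at the last frame the
smoothed trace stays above 1x noise (the trace that defines the event end
is ambiguous in the underlying procedure; this choice is flagged as an
interpretation). iGluSnFR2 events whose raw peak is below 0.2 dF/F0 are
discarded; iGluSnFR3 and RCaMP2 have no floor. Events never span
acquisition gaps; frame indices are 1-based with half-open
`[onset, offset)` events, the idiomatic R convention.

Event shapes are computed per event: the peak is searched in a 3-s window
from 1 s before to 2 s after onset (minimum peak separation 0.5 s, minimum
height the window median plus SD), and `A * exp(-t/tau)` is fitted from the
peak to the window end by Levenberg-Marquardt least squares. Events without
a qualifying peak or a finite, non-degenerate tau are flagged and excluded.

## Structure

Spine area is the summed intensity of spine-ROI pixels above background,
normalized per pixel by the mean intensity of dendritic pixels within 20 um
of the spine base, times the physical pixel area. Plasticity between
consecutive sessions uses the area ratio with inclusive boundaries
(enlargement >= 1.5, shrinkage <= 0.75); stability classification maps
3-session presence vectors to stable / eliminated (early-to-middle or
middle-to-late) / new / transient / excluded re-emergent. A spine present
on the first two sessions and absent on the third counts once as stable
for early-to-middle analyses and once as eliminated for middle-to-late,
matching the double-counting convention of the source analyses. Small
stable spines are selected by scanning lower-percentile cuts (10th--90th,
linear-interpolation quantiles) for the cut whose median ratio against the
eliminated areas is closest to 1 among cuts where a Wilcoxon rank-sum test
is non-significant; when the two criteria cannot be jointly satisfied the
best-ratio cut is returned with a warning.

## Movement-related classification

The per-spine statistic is the dot product of the binarized movement mask
with the continuous (0.5-s smoothed) dF/F0 trace; whether the dot product
should use the smoothed or raw trace is unstated in the source procedure,
and the smoothed trace used everywhere else in the pipeline is used here
too. The null distribution relocates the movement intervals uniformly at
random within the imaged frames -- durations preserved, non-overlap
enforced via the standard spacings construction -- 10,000 times in the full
analysis; a spine is movement-related when the observed value exceeds the
97.5th percentile of the null, a one-sided 2.5% rule. A circular-shift
null is available behind a flag. "Coincident" means at least one frame of
overlap between an event and a bout.

## Co-activity and functional clustering

A co-activity event is a maximal run of frames during which both binarized
traces are active (runs clipped at acquisition gaps, counted per block);
the rate is events per minute of *imaged* time, excluding gaps, so the
5-on/5-off acquisition does not deflate rates. Normalization divides by
the geometric mean of the two spines' event rates, making identical trains
score exactly 1. Pairs are restricted to the same dendritic branch and to
sessions where both spines showed at least one event. Distances are binned
in 5-um increments, half-open on the left (the 2.5-um bin covers
0 < d <= 5).

The co-activity environment of each eliminated spine comprises three
means: the eliminated-spine score (target vs its neighbors within 10 um),
the nearby environment (pairs among those neighbors, excluding eliminated
spines), and the distant environment (local pairs around spines farther
than 10 um, excluding the nearby group and anything within 10 um of other
eliminated spines).

## Spatial statistics

Local MRS density counts movement-related spines within 10 um of dendritic
distance and divides by the length actually surveyed,
`nf = min(10, left) + min(10, right)` clamped at branch ends (10 um <= nf
<= 20 um). Label-shuffle tests permute stable/eliminated labels across the
pooled spine set of all dendrites (positions and counts fixed), 1,000
shuffles, with one-sided p the fraction of shuffled statistics at or
beyond the observed value; a p of exactly 0 is reported as "< 1/n" in
output tables. Only stability labels are permuted; MRS flags stay fixed.
Nearest-neighbor distances to plasticity events exclude the target itself
and return missing when the dendrite carries no event of the queried kind.

## Event timing

Spine event onsets are matched to dendritic calcium event onsets within
+/-1 s, greedily by |delta-t| and one-to-one; delta-t = spine onset minus
dendrite onset, summarized per spine by the median (mean behind a flag).
The matching rule is this module's interpretation -- the source analyses
do not define one -- and is configurable. Soma-dendrite coupling matches
dendritic events to overlapping somatic events and reports the coincidence
fraction plus the Pearson correlation of peak-normalized amplitudes.

## Mixed models

Group comparisons use linear mixed-effects models fit by maximum
likelihood through `lme4`, e.g.
`Response ~ Stability + (1 | Animal) + (Stability - 1 | Animal)` and the
distance-interaction family for co-activity curves. ML (not REML) is the
default because fixed structures are compared by log-likelihood. Factors
use treatment coding with "stable" and "early" as references. p-values are
large-sample Wald z; the degrees-of-freedom method is not specified by the
source analyses, and Wald z is the simplest defensible default at these
sample sizes. Fits with one grouping level, or failed mixed fits, collapse
to ordinary least squares; singular fits are flagged but reported.

## Group comparisons at single-session scale

The source analyses pool hundreds of spines across dozens of animals, so a
per-spine summary (e.g. the median delta-t of each spine) is a natural unit
of comparison there. A single session carries only a handful of eliminated
spines, and a per-spine median over one or two matched event pairs is
dominated by spurious matches of independent events. The pipeline's
comparison table therefore reports group *estimates* pooled at the pair
level — the median of all matched lags per group, and pair-level means for
the environment contrast — while *p-values* come from spine-level
comparisons (rank-sum over per-spine medians with at least 3 matched
pairs; paired Wilcoxon over per-target environment scores), whose units
are closer to independent so the tests keep their nominal size on null
data. Both levels are present in the output: `lags` and `environment`
carry the per-spine tables, `comparisons` the pooled contrasts.

# The synthetic-session generator

`sim_config()` + `generate_session()` produce a complete session: lever
behavior with cue-triggered presses, spine and dendrite raw fluorescence on
a 58.3-Hz frame clock with 5-min-on/5-min-off gaps, geometry, areas,
labels, and full ground truth. The generative model:

* **Cluster events.** Each dendrite receives shared local events (Poisson,
  1.5/min) at random positions; a spine joins with probability
  `coupling * exp(-d / 10 um)`. Joining spines emit an event at the
  cluster time plus their own onset lag plus ~15 ms jitter.
* **Movement drive.** Ground-truth movement-related spines (40%) respond
  to a lever press with probability 0.3; half of presses also trigger a
  dendritic calcium event, emulating movement-locked spiking.
* **Dendritic events.** A cluster event recruiting >= 3 spines triggers a
  dendritic calcium event; independent global events occur at 0.5/min.
  The generative relation between spine co-activity and dendritic spiking
  is not characterized by the source data, so this k-of-cluster rule is a
  modeling choice, not an empirical claim.
* **Rate calibration.** Independent per-spine events top each spine's
  total expected rate up to `base_event_rate` (2/min), using the closed
  form of the mean join probability along the branch, so event-rate
  comparisons between groups are not confounded by the coupling structure.
* **Phenotypes.** Eliminated spines get `coupling * (1 - deficit)`
  (default deficit 0.5), an extra onset lag (+50 ms), and smaller areas
  (x0.7 on a lognormal base). Stable spines' lags are ~N(+10, 10) ms.
* **Waveforms.** Instantaneous rise to a lognormal amplitude (mean 1
  dF/F0) with exponential decay (tau 0.5 s; 1.5x slower for dendrites),
  clipped at block ends so events never span gaps, riding on a slowly
  drifting baseline (5% sinusoidal) with Gaussian dF/F0 noise (SD 0.1).

Defaults describe one session of 4 dendrites x 14 spines over 1500 s
(three 5-min imaged blocks, 25 imaged minutes). The eliminated fraction is
0.15 per dendrite -- higher than the ~8% of all imaged spines -- because
the analyses run on dendrites selected to contain at least one elimination
event, which enriches eliminated spines in the analyzed population. All
randomness comes from the config seed; identical configs give
bit-identical sessions.

What the generator does *not* emulate: pixel-level images and optics (ROI
pixel statistics appear only as tiny fixtures for the area computation),
motion artifacts, bleaching, multi-session learning dynamics beyond label
assignment, branch-specific dendritic events, and any dependence of event
waveforms on spine identity. Passing tests therefore demonstrate that the
pipeline recovers the statistical structure it assumes, not that real
imaging noise is fully represented.

# Numerical choices and degenerate inputs

* Rolling statistics use cumulative sums with partial windows at the
  edges; the event-detection smoother uses reflection padding.
* Quantiles are linear-interpolation (R type 7) throughout.
* A flat or NaN lever trace segments to zero bouts with a warning; traces
  below 1 kHz are an error.
* A dF/F0 trace with no negative values (noise cannot be estimated) makes
  `estimate_noise()` error; `compute_dff()` converts that to a missing
  sigma.
* Silent spines are excluded from pairs; a spine with no events has
  reliability 0 and undefined specificity.
* Non-positive baselines are an error naming the first offending frame.
* Interval relocation requires the movement time to fit in the session;
  the spacings construction keeps interval order fixed, which is
  exchangeable under the uniform placement used here.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use the defaults above
(20 effect and 20 null sessions for phenotype recovery; 500 spines x
1,000 shuffles for the permutation calibration; 200 replicates for shuffle
uniformity; 50 hierarchical datasets of 10 animals x 50 spines for the
mixed-model coverage), sizes chosen so each property is measured with
useful precision while a full run stays desk-scale.

# Known limitations

* The coupling deficit applies uniformly to joining any shared event,
  movement-locked drive included — that is what expresses "less co-active
  with neighbors despite similar overall activity". A side effect is that
  eliminated movement-related spines receive less movement-locked drive
  and are less often classified as MRSs in synthetic sessions, whereas
  the real data found the MRS fraction comparable between groups. A
  generator reproducing both facts simultaneously would need
  desynchronized-but-equally-probable movement responses; the simpler
  uniform rule was preferred and this discrepancy is accepted.

* The dot-product statistic uses the smoothed dF/F0; with very short
  events the choice of smoothing affects MRS calls near threshold.
* Onset lags are limited by the frame clock (17 ms); the +50 ms phenotype
  is ~3 frames, and per-spine medians are required to resolve it. Absolute
  timing between glutamate and calcium sensors is not interpretable; only
  relative differences between spine groups are.
* The event-end rule (smoothed trace falling below 1x noise) and the
  lag-matching rule are interpretations where the source procedure is
  silent; both are configurable.
* With few eliminated spines per session the environment scores can be
  missing (no eligible pairs); group comparisons drop such spines.
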