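---
title: "Burst detection methods and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst detection methods and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstlab)
```

burstlab detects bursts — runs of three or more spikes in quick
succession — in single-channel spike trains, and benchmarks detectors
against simulated trains whose bursts are known by construction. This
vignette is the package's account of the methods: the models behind
each detector, the simulator families, the parameters that matter, the
numerical choices, and the design decisions taken where the published
method descriptions leave room.

## Conventions

Time is in seconds everywhere, including files; mixing seconds and
milliseconds across parameters is a classic source of silent error, so
the package normalizes once at the boundary. Spike indices are 1-based
and burst index ranges inclusive, the natural R convention. Burst time
intervals are closed `[begin, end]`. Every detector enforces a global
minimum of three spikes per burst, and duplicate spike times are
rejected on input because the rank-based methods require strictly
positive ISIs.

## The detectors

**MaxInterval (`mi`).** Five fixed thresholds: a burst is seeded by an
ISI at or below the maximum beginning ISI (0.17 s), extended while ISIs
stay at or below the maximum end ISI (0.3 s), adjacent bursts closer
than the minimum interburst interval (0.2 s) are merged, and bursts
shorter than 0.01 s or with fewer than 3 spikes are dropped. The merge
step is iterated to a fixed point, so merging two bursts can enable a
further merge. MaxInterval is the only method with no data-derived
quantity; the same parameters apply to every electrode of a recording.

**logISI histogram (`logisi`).** The histogram of log₁₀ ISIs is built
with 10 bins per decade and smoothed with a Gaussian kernel (sd 2 bins)
before peak finding; both are exposed as parameters since the original
peak-finding procedure is not fully specified in print. The largest
peak at or below the 100-ms maximum cutoff is the intraburst peak — no
such peak, no bursts. For each later peak the minimum in between is
scored with the void parameter `v = 1 - h_min / sqrt(h_peak1 * h_peak2)`,
and the ISI at the first minimum with `v >= 0.7` becomes the burst
cutoff. If that cutoff exceeds 100 ms (or none is found), burst cores
are detected at 100 ms; when a larger cutoff exists the cores are then
extended to absorb spikes within the cutoff of each edge, merging cores
that meet.

**Cumulative moving average (`cma`).** The CMA of the ISI histogram is
the running mean of bin counts; the skewness of the CMA curve (treated
as a distribution over bin centers) selects the coefficient pair
(α₁, α₂), and the burst cutoff is the ISI of the bin where the CMA is
closest to α₁·CMA_max, scanning from the CMA peak onward. Scanning from
the peak matters: on burst-dominated trains the ISI histogram has its
mode in the first bin and the CMA only descends, so an unrestricted
closest-value scan would land in the first few bins and truncate every
burst. Only burst cores are reported; the original burst-related-spike
extension (the α₂ cutoff) is deliberately not applied. The histogram
bin width is the one free constant of this method and defaults to
0.1 s: at millisecond resolution the α₁ crossing of the descending CMA
sits at a few milliseconds and the detector collapses on exactly the
regular-bursting trains it is known to handle well, whereas 0.1-s bins
reproduce the method's published profile — high recall on regular and
high-frequency bursting, substantial spurious detection on nonbursting
and nonstationary trains. The `hipsc` preset adds the authors' post-hoc
screen: a train whose detected bursts average more than 5 s or more
than 50 spikes is declared nonbursting.

**Poisson surprise (`ps`).** The null model is a homogeneous Poisson
process at the train's mean rate λ. The surprise of an interval of
length T holding N spikes is `S = -log P(Poisson(λT) >= N)`, evaluated
in log space (`ppois(..., log.p = TRUE)`) so values up to several
hundred are exact. Candidate bursts are seeded on runs of at least two
ISIs below half the mean ISI, then grown by surprise maximization: the
end is extended to the best of the next 10 spikes (the bounded
lookahead of the original procedure) repeatedly, the start trimmed
likewise, and finally single-spike moves at either end are applied to a
fixed point, so every reported burst is locally surprise-maximal.
Overlaps are resolved greedily by descending S. Default threshold
`-log(0.01) ≈ 4.6`.

**Rank surprise (`rs`).** ISIs are ranked across the train (mid-ranks
on ties, which preserves the rank-sum null). Only ISIs at or below the
75th percentile may join a burst; within each maximal run of such ISIs
every sub-window of ≥ 2 ISIs is scored by
`RS = -log P(U_1 + ... + U_q <= ranksum)` with `U_i` i.i.d. uniform on
`{1..N}`. The exact null CDF is computed by convolution for `q <= 12`
and by a Gaussian approximation with continuity correction above
(mean `q(N+1)/2`, variance `q(N²-1)/12`); at the crossover the two
agree to well under a percent in the region where detection decisions
are made. Candidates are accepted greedily by descending RS without
overlap, ties to the earlier start. The 75th-percentile gate is the
method's defining structural limit: at most a quarter of a train's
ISIs can ever be inside bursts, which is why the method recovers under
half of the bursts on trains that are almost entirely bursts.

**Robust Gaussian surprise (`rgs`).** Bursts are low outliers from a
"central distribution" of log ISIs. Each train's log ISIs are centered
by the train median, centered values are pooled across all supplied
trains (on an MEA recording, across electrodes — the only detector
with a cross-channel contract), and the central distribution is
estimated robustly: center = median, spread = MAD scaled by 1.4826 so
it estimates a Gaussian sd. The −2.58 multiplier is applied to this
scaled MAD; at Gaussian tails 2.58 sd is the two-sided 1% point, which
is consistent with the −log(0.01) surprise threshold, and the scaling
choice is exposed as a parameter. Runs of sub-threshold ISIs seed
bursts, extended one ISI at a time while the Gaussian sum surprise
`GS = -log Φ((Σx_i - kμ)/(σ√k))` increases. Pooling makes the detector
invariant under duplicating the input trains, which the tests verify.

**ISI rank threshold (`irt`).** A heuristic two-threshold rule. The
spike-count cutoff θ_C is the smallest integer C whose empirical
exceedance probability over the disjoint 1-s windows of the recording
is at most 0.05 — the tail reading of the cutoff, since a cutoff needs
a tail; a density reading would not define one. A burst starts at a
spike whose forward 1-s count exceeds θ_C when its next ISI has
normalized rank below 0.5, and runs to the first spike whose forward
count drops below θ_C/2. Forward windows at the end of the train are
truncated and use raw counts without rescaling.

## The simulator

The generators produce the spike-train families the benchmark
scenarios require, each as a `labeled_train` with exact ground truth:

* nonbursting controls: homogeneous Poisson ISIs and gamma ISIs
  (shape α, rate β; renewal rate β/α), and an inhomogeneous Poisson
  train realized by thinning. For the nonbursting scenarios the
  smallest 10% of ISIs are removed (deleting the later bounding spike
  of each) to eliminate chance burst-like runs.
* Poisson bursting: burst centers from a Poisson process (rate λ),
  Poisson-distributed spike counts per burst (mean n), spike positions
  uniform over a window of range r centered on the burst center.
  Where two bursts overlap — their windows `center ± r/2` intersect —
  only the first is kept and the later burst is dropped whole; judging
  overlap on the model window rather than the realized spike extent,
  and against every earlier burst rather than only the kept ones, is
  what reproduces the expected ~91% in-burst composition of the noisy
  scenario below (realized-extent, kept-only variants land at ~93.5%).
  Bursts reaching outside `[0, duration]` are dropped, not clipped.
  Burst sizes below three are redrawn — a smaller "ground-truth burst"
  would be undetectable by construction and would poison true-positive
  accounting — with `allow_small = TRUE` to disable.
* nonstationary bursting: per-burst n ~ U(5, 18) and r ~ U(0.3, 3) s,
  keeping only bursts with within-burst rate above 5 Hz. The rate is
  spike count over realized extent; a zero-extent burst passes, its
  rate being unbounded.
* noisy bursting: a Poisson bursting train superposed with gamma-ISI
  noise (trimmed as above); noise spikes within 0.5 s of any kept
  burst's realized limits are deleted, so burst and noise spikes never
  interleave and membership labels are exact.

The benchmark scenarios (`sim_property_train`, ids `D4`–`D11`) fix the
parameter sets: Poisson 1 Hz; nonbursting 0.5 Hz Poisson alternating
with gamma(1, 0.5); inhomogeneous `1 + t/300` Hz; regular short bursts
(0.2 Hz, 5 spikes, 0.3 s); nonstationary bursts (0.3 Hz); long bursts
(0.1 Hz, 18, 3 s); high-frequency bursts (1 Hz, 10, 0.5 s); noisy
bursting (0.5 Hz, 8, 0.8 s, gamma(1, 0.5) noise, 0.5-s margin). Trains
are 300 s and scenarios use 100 trains by default. Seeding is per
train: a substream seed is derived deterministically from the master
seed, the scenario and the train index, so any single train can be
regenerated in isolation and whole runs are bitwise reproducible.

What the simulator does *not* emulate: refractory periods (ISIs can be
arbitrarily small), electrode noise and spike-sorting errors, network
(array-wide) bursts, and slow nonstationarities other than the linear
ramp. Passing the benchmark therefore shows a detector handles these
idealized regimes, not that it is optimal on any particular
experimental preparation; for real recordings the evaluation tools
accept visually annotated bursts as the reference instead.

## Evaluation

`tp_fp_spike_fractions` scores detection against ground truth: the
true-positive fraction is the share of within-burst spikes detected,
the false-positive fraction the share of noise spikes flagged. Empty
denominators yield `NA`, never a silent 0. `sensitivity_specificity`
applies the same definitions against annotated intervals.

`roc_sweep` traces sensitivity against false-positive rate over a
per-method parameter grid (probability cutoff for the surprise
methods, count-tail level for IRT, maximum cutoff for logISI, the
beginning ISI for MaxInterval with the end ISI held 0.130 s above, a
single point for CMA, which has no natural parameter to vary) and
scores each method by its minimum distance to the perfect-classifier
corner (0, 1) — not the area under the curve, because the three-spike
minimum and each method's structural caps keep most curves from
spanning the full range. Sensitivity is averaged per train by default
(each annotated train weighted equally); pooled-spike averaging is
available with `pooled = TRUE`.

`burst_mask` bins the bursting state into 50-ms bins (6000 bins for a
300-s recording) and `hamming_distance_fraction` gives the fraction of
bins on which two detectors disagree — a proper metric on masks.
`burst_summary` reports the descriptive statistics used for
developmental comparisons: fraction of spikes in bursts, mean burst
duration, burst count, and the CV of interburst intervals. The IBI is
measured end-to-start (onset-to-onset is available as an option; the
choice is not standardized in the literature) and the CV is `NA` below
three bursts. A detected burst "recovers" a ground-truth burst when
their time intervals intersect, with no one-to-one matching — the
burst-count ratio is reported separately so over-segmentation remains
visible.

## Numerical choices and degenerate inputs

* Poisson tails via `ppois(log.p = TRUE)`; no underflow for surprise
  values into the hundreds. Surprise is clamped at 0.
* Exact rank-sum convolution switches to FFT above a size cutoff and
  clamps tiny negative FFT residue at 0; the exact/Gaussian crossover
  is `q = 12` ISIs.
* Detectors given fewer than three spikes return an empty `burst_set`,
  never an error; a burst may begin at the first and end at the last
  spike of a train.
* A constant pooled log-ISI sample makes the RGS central distribution
  degenerate (zero spread); the detector then reports no bursts.
* CMA argmin ties take the first (smallest-ISI) bin at or after the
  peak. Exact ties in simulated spike positions are redrawn.
* Benchmark problem sizes follow the study conditions: 100 trains of
  300 s per scenario; the unit tests exercise the same code on smaller
  train counts.

## Known limitations

The logISI peak-finding step is a reimplementation (Gaussian-smoothed
histogram, strict local maxima) of a procedure whose original is only
sketched in print; its two knobs are exposed rather than hidden. The
CMA bin width is likewise a package choice, as discussed above. The
hidden semi-Markov model detector family is out of scope — it is
nondeterministic and defined by an external sampler — but external
implementations can be attached through `register_detector` under the
same `burst_set` contract and participate in every evaluation tool.
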