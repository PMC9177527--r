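---
title: "Measuring single-molecule replication fork speeds from BrdU pulse-chase traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-molecule replication fork speeds from BrdU pulse-chase traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(replifork)
library(dplyr)
```

## The measurement problem

When asynchronously growing cells expressing a thymidine-salvage pathway are
exposed to a brief pulse of the thymidine analogue BrdU (typically 2 min at
100 uM) followed by a thymidine chase, every replication fork that was
elongating during the pulse deposits a BrdU track in the nascent strand.
Nanopore sequencing of the resulting genomic DNA, basecalled with a
modification-aware model, yields for every read a probability of BrdU at
each thymidine site. A fork shows up as an asymmetric signal: a stretch of
background (DNA replicated before the pulse), a steep rise while
intracellular BrdU accumulates, and a shallower decay as the chase dilutes
it. The rise-then-decay asymmetry orients the fork; the distance between
the start of incorporation (`X0`) and the start of the chase (`X1`),
divided by the pulse duration, is the fork speed averaged over the pulse:

\[
v = \frac{|X_1 - X_0|}{t_\mathrm{pulse}} \qquad \text{(bp/min)}.
\]

`replifork` implements the full measurement chain — trace parsing,
smoothing, piecewise-linear segmentation, pattern-based fork calling,
genome-wide aggregation — together with a simulator of pulse-chase fork
signals with ground truth, and a deconvolution procedure that estimates the
underlying true speed distribution from the biased, dispersed measured one.

## From raw traces to forks

**Input.** Per-thymidine BrdU probabilities attached to reference
coordinates, either from a modified-base BAM (MM/ML tags, decoded as
`p = (score + 0.5)/256` and projected through the CIGAR) or from a plain
TSV. Mapping gaps longer than 100 bp are recorded; a fork whose span
crosses such a gap is discarded, because a mapping discontinuity under a
track corrupts its length. All coordinates in the package are 0-based
half-open.

**Smoothing.** Two stages: a centered 100 bp rolling mean over the
available probabilities, then a Gaussian-weighted rolling mean with a
2.5 kb window, evaluated densely so that non-thymidine positions carry a
value. Both stages renormalise their weights over non-missing values. The
first and last 2.5 kb of every read are dropped (reads under 5 kb are
excluded entirely — they cannot contain a complete fork plus flanks). The
Gaussian kernel is truncated at half the window, with standard deviation
`window/6` (~417 bp) so the truncation sits at three standard deviations;
both the window and the sd are exposed in `fork_params()`.

**Segmentation.** The smoothed signal, evaluated on a 10 bp lattice, is
simplified with the Ramer-Douglas-Peucker algorithm at a vertical tolerance
of 0.1 signal units. Deviation is measured on the signal axis only:
abscissae are in bp (10^3-10^5) while the signal lives in [0, 1], so a
Euclidean point-to-chord distance would be dominated by the x axis. The
10 bp lattice quantises breakpoints by at most ~10 bp (~5 bp/min on a
speed) and makes the dense evaluation affordable; the test suite checks
that lattice and dense breakpoints agree to under 20 bp. Ties in the
deviation maximiser break to the leftmost point, making the segmentation
deterministic. Segments are classified from their total amplitude change
and mean level: `P` (rise >= 0.05), `N` (fall >= 0.05), otherwise `B`
(flat, mean below the background threshold 0.02) or `A` (flat, above).
The background threshold can be re-estimated per experiment with
`estimate_background_threshold()`, which finds the density valley between
the background and labelled modes of per-kilobase mean BrdU values; the
kernel bandwidth is halved relative to the default because the background
mode is much sharper than the labelled one, and the fit falls back to 0.02
when the density is not clearly bimodal.

**Fork calling.** Rightward forks match `B P (P|A)* N+` — background
replicated before the pulse, a rising pulse track possibly interrupted by
flat above-background noise segments, then chase decay — and are rejected
when the next segment after the final `N` is a `B` (chase DNA retains
above-background BrdU, so a return to background means the signal was not
a complete fork). Leftward forks match the mirrored `P+ (N|A)* N B` with
the mirrored rejection. The two patterns are searched independently
(non-overlapping matches, left to right) and the exclusions applied per
match; surviving matches can share at most a boundary `B` segment. This
excludes incomplete tracks and the symmetric signals of fork pairs born or
terminated inside the pulse, whose labelling time is unknown. `X0` and
`X1` are the fitted junction positions; `d_y` is the fitted signal
difference between them. Adjacent diverging (leftward-then-rightward)
pairs yield an initiation event at the midpoint of the facing `X0`s;
converging pairs a termination at the midpoint of the facing `X1`s.
Mapping strand then classifies each fork as leading- or lagging-strand
synthesis: nanopore reads the nascent strand, so a rightward fork on a
forward-mapped read is leading-strand synthesis (flip with
`leading_convention = "template"` if your library preparation inverts
this).

```{r one-read}
sim <- simulate_single_forks(3, speeds = c(1800, 2400, 2900),
                             noise = noise_params(), seed = 42)
plot_trace(sim$traces[1, ])
fc <- call_forks(sim$traces)
tidy(fc) %>% select(read_id, X0, X1, direction, speed, d_y)
sim$truth %>% select(read_id, v_true, direction)
```

## The simulator

The simulator is the package's test bed: it produces reads with known fork
speeds through the same kind of signal the detector sees.

**Kinetics.** Intracellular BrdU level is zero before the pulse, rises as
\(As(t) = M(1 - e^{-t/\tau_1})\) during it, and relaxes as
\(Ds(t) = As(t_\mathrm{pulse}) + (m - As(t_\mathrm{pulse}))(1 -
e^{-(t-t_\mathrm{pulse})/\tau_2})\) afterwards. A fork travelling at speed
`v` converts this time course into space: `BrdU(x) = b(x / v)`. Defaults:
`M = 0.62`, `tau1 = 1.25` min, `m = 0.10`, `tau2 = 5` min, `t_pulse = 2`
min. They were chosen once, to reproduce the canonical track shape of
pulse-labelled yeast reads: a peak of about 0.5 at the end of the pulse, a
chase relaxing towards about 0.1, and an ascending slope steeper than the
descending slope at every point of the track. The last property
constrains `tau1`: with `tau1` well below the pulse duration the rise
saturates into a flat top, which neither matches the described track shape
nor leaves the chase-start position recoverable. Real fork-to-fork
variability is emulated by mean-preserving log-normal jitter with 20%
coefficient of variation on all four parameters (`sample_kinetics()`).
Real kinetic parameters vary with correlations we cannot know; this
independent-jitter stand-in is the main respect in which the simulator is
weaker than a library fitted to experimental forks.

**True speeds.** The default sampler is a two-component Gaussian mixture
(mean 2486 sd 150 with weight 2/3, mean 1800 sd 700 with weight 1/3,
truncated to 50-5000 bp/min), a stand-in for the narrow dominant mode plus
dispersed tail expected of unperturbed yeast forks.

**Noise.** An empirical read-level model: a per-read background offset
drawn from a log-normal (shape 1.98, location -4.09e-06, scale 0.001,
fitted on BrdU-free DNA), redrawn outside [1e-7, 0.2]; `signal + offset`
truncated at 1; only a Bernoulli(0.23) subset of positions (the
thymidines) carries a value; and each thymidine emits `Binomial(n, p)/n`
with `n` uniform on {1, 2, 3}, reproducing the bimodal per-site calls of
modification basecallers. Noise-free mode emits the exact profile at every
position. `noise_autocorrelation()` summarises the spatial correlation of
the high-frequency signal component for comparing simulated with real
noise.

**Multi-fork genomes.** 300 kb segments carry 6 uniformly placed origins
(one per 50 kb on average) firing at times uniform on 0-30 min, all forks
of a segment sharing one speed. The origin/firing configuration is redrawn
until every origin fires actively (with equal speeds the replication time
field is \(T(x) = \min_j (t_j + |x - x_j|/v)\), so origin `k` is active iff
it fires before any fork reaches it), giving exactly 12 forks; redrawing
the configuration for a fixed speed rather than jointly keeps the segment
speed distribution equal to the sampler's, which a joint rejection would
skew low (fast forks passively replicate late origins far more often).
The pulse moment is uniform between the earliest firing and three fifths
of the latest. BrdU is laid down from the local replication time, and the
segment is sliced into reads with truncated log-normal lengths (sdlog 0.5,
median 13 kb, mean ~15 kb, truncated to [5, 300] kb) to match the length
of typical experimental nanopore reads. The slicing length
scale exists purely to make simulated molecules the length of experimental
ones, so the default is set to reproduce that mean length. All seeded runs are
bit-reproducible.

## Accuracy, and what the simulations do and do not show

`evaluate_single_forks()` and `evaluate_genome_forks()` run
simulate-measure-match experiments. At the package defaults (problem
sizes: 10,000 reads per condition in `scripts/acceptance.R`, reduced in
the test suite since medians and IQRs are sample-size free):

* on clean single-fork reads the median speed error is a few bp/min with
  an IQR under ~120 bp/min, and orientation is essentially perfect;
* the full noise model widens the IQR to ~300-400 bp/min while the median
  error stays within a few tens of bp/min;
* errors are speed-dependent: slow forks are overestimated and fast forks
  underestimated, with the crossover near the distribution mode.

The speed dependence has a geometric origin worth understanding before
interpreting real data. The 2.5 kb smoothing spreads the track onset, and
the coarse (epsilon = 0.1) piecewise simplification places the `B`/`P`
junction partway up that spread foot, a few hundred bp outside the true
incorporation start — and further out the longer the flat background
flanking the track, because the deviation geometry of the simplification
depends on the chord lengths. On multi-fork reads, where the chase is
usually not truncated by the read end, the compensating inward shift of
`X1` is absent and the median error is more positive than on single-fork
reads (roughly +100 bp/min at the defaults), and the relative error in the
slowest bins of the 1000-3000 bp/min range can exceed 10%. Pipelines whose
simulated forks use kinetic parameters fitted to real forks *through the
same measuring procedure* absorb part of this bias into the fit, and
per-bin recalibration against a simulated response (what the
deconvolution's response library provides) removes most of it; the raw
per-fork speeds carry it. Nothing in these simulations validates the
modification basecaller itself: traces here are generated from the model
the detector assumes, so passing tests show the measurement chain is
internally accurate, not that any basecaller is.

## Estimating the true speed distribution

Measured speeds are a blurred, biased image of true speeds. Because the
blur can be characterised on simulated reads, it can be deconvolved.
`build_response_library()` simulates reads with true speeds uniform on
(50, 5000) bp/min, measures them, assigns each (true, measured) pair to
the 44 overlapping true-speed classes `v_k = k * 100` bp/min (window width
400 bp/min — the overlap guarantees class occupancy), and summarises each
class's measured-speed distribution as a five-component Gaussian mixture.
`deconvolve_speeds()` then finds non-negative class weights whose mixture
of responses best fits (least squares on 100 bp/min histogram bins — the
loss is convex and solved exactly by non-negative least squares) the
observed speed histogram, normalises them to a probability vector,
averages the weight sets over independently simulated libraries (five by
default in `run_deconvolve()`), and fits a six-component Gaussian mixture to the
averaged discrete distribution for a continuous estimate. The reported
mode is the mixture density's maximiser on a 1 bp/min grid, which is
deterministic. Mixture fits use deterministic model-based initialisation
(an evenly spaced subset of the sorted sample above 2000 points, where
quadratic-cost agglomeration would be wasteful) and fall back to fewer
components if a fit degenerates.

`roundtrip_check()` closes the loop: simulate reads from the estimated
true distribution, measure them, and compare with the originally observed
distribution by total variation distance on the same bins. Self-consistent
estimates give distances below ~0.1 at a few thousand reads; the sampling
noise floor of the statistic at that size is a few hundredths.

```{r deconv-sketch, eval = FALSE}
libs <- lapply(1:5, function(r) build_response_library(100000, seed = r))
est <- deconvolve_speeds(observed_speeds, libs, seed = 99)
glance(est)      # mode of the continuous fit, mass near the mode
autoplot(est)    # discrete weights + continuous density
roundtrip_check(est, observed_speeds, n_reads = 20000, seed = 100)
```

## Genome-wide aggregation

* `compute_rfd()` bins rightward and leftward fork-track coverage
  (default 100 bp bins) and returns `RFD = (R - L)/(R + L)`, missing where
  nothing is covered.
* `speed_map()` reduces forks to their span midpoints and, per window of
  each width (1-10, 15, 20 kb), reports the fork count, median speed with
  its 98% confidence interval (exact binomial order-statistic interval),
  and one-sided Mann-Whitney-Wilcoxon p-values against the genome-wide
  speed distribution, Holm-corrected separately for the slower and faster
  families across all windows of all widths; significance is called at
  adjusted p < 0.01, and empty windows are `na`. The genome-wide reference
  includes the tested window's own forks; at genome scale the difference
  from excluding them is negligible.
* `shuffle_envelope()` permutes speed labels across fixed fork locations
  (1000 times by default) and returns per-window median and 1st/99th
  percentile bands — the local variation expected under spatial
  homogeneity.
* `feature_overlap_speeds()` groups forks by overlapped features (minimum
  one nucleotide), drops forks overlapping more than one feature from
  grouped summaries (exclusive-level rule), and, given an RFD track,
  labels stranded features co-directional or head-on from the sign of the
  mean RFD over the feature.
* `speed_vs_timing()` computes each fork's coverage-weighted mean
  replication timing and Spearman's correlation between speed and timing.

Cross-condition inference (mixed-model contrasts between samples) is out
of scope; `summarize_sample()` provides the per-sample descriptive
quantities those comparisons start from.

## Degenerate inputs and numerical choices

Reads shorter than 5 kb, with fewer than three segments, or all
background produce no forks rather than errors. Interior missing values in
a smoothed signal are linearly interpolated before simplification (the
simplifier itself refuses non-finite input). Smoothed values are clamped
to [0, 1] against floating-point drift. `measure_speed()` rejects
`X0 == X1`, which cannot arise from a valid pattern match. The
convolution core is FFT-based and exact to ~1e-10 against the direct
windowed sums; the box stage uses cumulative sums. Permutation and
simulation functions take explicit seeds and are bit-reproducible;
nothing in the package depends on ambient RNG state unless a seed is
omitted.

## Limitations

* Fork pairs initiating or terminating within the pulse are excluded by
  design; coverage dips at strong origins are expected.
* Per-fork speeds inherit the landmark-placement bias discussed above;
  comparisons between conditions are robust to it, absolute slow-fork
  speeds less so. The deconvolution path is the bias-corrected route.
* The kinetic stand-in cannot reproduce correlated parameter variation of
  real fork libraries; accuracy figures on simulated data are exact for
  the simulator's world and approximate for any real dataset.
* rDNA-like tandem repeats need a dedicated reference construction and are
  outside what this package addresses.
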