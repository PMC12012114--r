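---
title: "Signal-based demultiplexing of nanopore direct RNA sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-based demultiplexing of nanopore direct RNA sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtwdemux)
```

## The problem

Nanopore direct RNA sequencing (dRNA-seq) threads native RNA 3'-to-5'
through a protein pore; the ionic current trace (the "squiggle") is decoded
by an RNA basecaller. Multiplexing requires barcodes, but the barcode sits
in the DNA reverse-transcription adapter (RTA) ligated to the RNA 3' end,
and the RNA basecaller cannot read DNA. The barcode must therefore be
recognized directly in the raw current signal.

`dtwdemux` implements a complete signal-space barcoding stack:

1. a squiggle **simulator** that generates labeled reads with the
   three-part anatomy of a dRNA-seq trace (DNA adapter, poly(A) plateau,
   RNA body), so everything downstream is testable without sequencing data;
2. **signal preprocessing**: poly(A)-onset detection, event segmentation,
   robust normalization, and a 25-value barcode *fingerprint*;
3. a **DTW-kernel SVM classifier** with an explicit noise class, calibrated
   class probabilities, a confidence score, and accuracy-targeted
   confidence thresholds;
4. **de novo barcode design** maximizing pairwise DTW separation
   (a Maximal Diversity Problem);
5. a **barcode-balancing adaptive-sampling simulator** with dynamic
   rejection thresholds and Gini-coefficient evaluation.

## The raw-signal model and the simulator

A pore event (one k-mer occupying the pore) emits a roughly constant
current level for a stochastic *dwell time*. The simulator
(`simulate_read()`) composes a read from per-base expected levels:

* **adapter**: a fixed leader sequence shared by all classes followed by
  the 18-nt barcode, converted to levels through a k-mer model (5-mers by
  default), in 3'-to-5' translocation order;
* **poly(A)**: a long plateau at a fixed level (default 108 current units,
  60 nt), the low-variance landmark separating adapter from RNA;
* **RNA body**: a clipped Gaussian random walk, standing in for arbitrary
  transcript signal.

Dwell times are negative-binomial with mean `sample_rate /
translocation_speed` (3012 Hz / 70 nt/s by default, about 43 samples per
base) and a dispersion knob; dispersion 0 gives deterministic dwells, which
the degenerate-case tests exploit. Gaussian measurement noise (default sd
2.5 current units, a realistic pore-noise magnitude relative to a 60-130
unit level range) is added on top. An RNA004-like preset
(`sim_config_rna004()`) changes only the sampling rate and motor speed.

The bundled k-mer model is synthetic - levels drawn uniformly in [60, 130]
under a fixed seed - so no download is ever required. It reproduces the
*statistical* structure the pipeline relies on (distinct, reproducible
per-k-mer levels), not any pore chemistry; conclusions from passing tests
therefore concern the algorithms, not real-pore error modes such as
context-dependent noise, baseline drift, or systematic dwell biases.

**Noise reads.** Real runs contain irregular reads (stalled adapters,
blocked pores, inaccurate DNA/RNA boundaries). The generator corrupts a
configurable share of reads with three equally likely operators: a stalled
adapter whose barcode tail is replaced by a long poly(A)-like plateau (the
apparent boundary comes too early), an adapter truncation losing at least
half the adapter, and a poly(A) deletion. The first two were deliberately
designed as *boundary-type* irregularities: flat stretches inserted
mid-adapter turn out to be nearly invisible to the last-25-segment
fingerprint (dynamic time warping traverses constant runs almost for free),
whereas early-boundary reads produce compressed, over-segmented
fingerprints that are genuine outliers - which is the phenomenon the
noise-class selection (below) relies on. Poly(A)-deleted reads mostly fail
boundary detection and exercise the QC path instead.

## Preprocessing and the fingerprint

`detect_boundaries()` finds the poly(A) plateau as the longest run of
200-sample windows whose level lies in a poly(A) band (default 95-125) and
whose variance is below `polya_var_mult` (default 4) times the minimum
rolling variance of the read - the minimum rolling variance estimates the
measurement-noise floor without assuming how much of the read is plateau,
so the same rule works on complete reads and on streamed prefixes. The
onset is then refined by maximizing the two-segment mean-shift
log-likelihood-ratio statistic in a tight window around the coarse plateau
start; a tight window keeps adapter-internal event boundaries out of the
statistic (with a wide window they dominate it). Missing plateaus set QC
flags; they never raise errors, because such reads must flow to the
noise/unclassified path.

`segment_adapter()` partitions the adapter span into `round(50 * 1.10) =
55` events: a Welch t-statistic between adjacent 15-sample windows is
computed at every interior position, and the 54 highest-t positions are
kept greedily (descending t, ties to the lower index) subject to a
3-sample minimum segment length; if the greedy pass cannot place enough
boundaries the rest go to midpoints of the largest gaps, deterministically.
The 10% over-segmentation protects against missed events; surplus
boundaries merely duplicate levels, which the downstream DTW absorbs
cheaply. Segment means are normalized over all 55 segments - median/MAD by
default with the 1.4826 consistency factor, robust against the extreme
values that irregular reads produce - and the **last 25** normalized
segment means form the fingerprint: the barcode occupies the temporal tail
of the adapter, directly before the poly(A). Whether to normalize before
or after trimming is a genuine choice; normalizing before (over all 55)
uses the whole adapter as the scale reference and is what this package
does.

## DTW distance and kernel

The fingerprint distance is classical dynamic time warping with squared
local costs, steps (1,0), (0,1), (1,1), anchored ends and a final square
root, optionally banded (Sakoe-Chiba). For equal-length series it is
bounded above by the Euclidean distance. The classifier's kernel is

$$K(s_1, s_2) = \exp(-\gamma \cdot \mathrm{DTWD}(s_1, s_2)), \qquad
\gamma = 1.2 .$$

This kernel is not guaranteed positive semidefinite. The SVM layer
therefore accepts indefinite kernel matrices as-is (libsvm behavior), with
a one-shot diagonal jitter (1e-8) retry on solver failure. A related
numerical choice: the SMO convergence tolerance defaults to 0.01 rather
than libsvm's 0.001, because on indefinite kernels the tight tolerance can
cycle for minutes on heterogeneous class pairs (barcode vs. noise) with no
measurable change in the fitted classifier.

## Classifier, probabilities, confidence

`train_demux()` fits a one-vs-one SVM on the precomputed kernel matrix
(binary machines via kernlab/libsvm). Class-membership probabilities are
calibrated per class pair by Platt scaling - a logistic map fitted to
decision values obtained from an internal stratified 5-fold
cross-validation, with Platt's regularized targets - and combined into a
simplex by pairwise coupling (the iterative libsvm scheme of Wu, Lin &
Weng). This layer is implemented in the package: kernlab's built-in
multiclass probability model mishandles precomputed kernel matrices, which
is easy to verify by comparing its probability argmax against its own
decision-value predictions.

The **confidence score** of a prediction is the gap between the two
largest class probabilities. Reads whose top class is the noise class are
reported as `noise` regardless of the cutoff (and excluded from accuracy
assessment); reads below the cutoff are `unclassified`; at cutoff 0
everything is assigned. A tie between the top two probabilities gives
confidence 0 and is unclassified at any positive cutoff.

**Calibration** (`calibrate_demux()`): for each barcode $b$, the baseline
error rate $E_b$ (percent) is measured among held-out reads *predicted* as
$b$; for a target accuracy $A_t$ the confidence threshold is the
linear-interpolation $q$-quantile of the misclassified reads' confidences
with $q = 1 - (100 - A_t)/E_b$, clamped to 0 when the baseline already
meets the target. Scores above the threshold are retained. The
implementation keeps the two clamping branches ($E_b = 0$ and $q < 0$)
explicit because they are the common case for well-separated barcodes.

A note on the accuracy-versus-cutoff curve: with a fixed set of surviving
high-confidence errors, accuracy $1 - e/n$ necessarily dips by about $1/n$
as the denominator shrinks, so the trade-off curve is monotone only up to
one-read granularity; the tests assert it at that granularity.

## Training-set construction

Labeled fingerprints are subsampled to a compact training set:

* **noise class**: for each read, the median DTW distance to (up to 200)
  reads of *other* classes is robust-Z-scored (median/MAD, Eqs. of the
  robust Z-score); the top 400 reads above the cutoff (default 3.5, the
  classical robust-outlier convention) become the noise class. Irregular
  reads are far from every class, clean reads are far only from other
  classes. In simulation roughly three quarters of the selected instances
  are truly corrupted reads; the remainder are clean-generated reads whose
  boundaries genuinely misdetected - precisely the reads the noise class
  is meant to absorb, so this is a feature of the selection, not leakage.
* **per barcode**: 80 instances by greedy *maximal* diversity on the
  within-class DTW matrix (farthest-pair seed, then maximal summed
  distance), 80 by the mirrored greedy *minimal* diversity (closest-pair
  seed), and 240 sampled uniformly (stratified across replicate groups
  when present) - 400 per barcode in total, capturing the extremes and the
  bulk of each class's signal distribution.

## De novo barcode design

Targets are square/sine hybrid waveforms over a grid of frequencies (1-4
cycles), phases and signs, median-centered and sd-scaled (the MAD of a
near-two-valued square wave is degenerate, so the robust scale uses the
sd), greedily thinned to the 12 mutually most DTW-distant patterns.
Candidate barcodes are sought by stochastic hill-climbing: random valid
18-mers built by walking the overlap graph of *direction-robust* k-mers
(k-mers whose model level changes by at most half the model's
inter-quartile range when the k-mer string is reversed - a proxy needed
because no 3'-to-5' DNA model exists), mutated one base at a time,
accepted when the DTW distance between the candidate's normalized
predicted levels and the target decreases. The 50 best distinct sequences
per target give a pool of 600.

Selection solves the Maximal Diversity Problem - choose $k$ of $M$
candidates maximizing the summed pairwise DTW distance, an NP-hard
problem - with a greedy construction (globally farthest pair, then maximal
summed distance to the selection) refined by 1-swap local search; an
exhaustive solver is available for instances with $\binom{M}{k} \le 10^6$
and anchors the heuristics in tests. Duplicate sequences may appear in the
pool (counts are kept exact) but never in the final selection.

## Adaptive sampling and barcode balancing

`stream_reads()` replays a read set in 100 ms chunks (about 300 samples at
3012 Hz) across simulated channels. `live_classify()` accumulates chunks,
watches for the poly(A) onset with a reduced plateau-evidence requirement
(300 samples, since only the beginning of the plateau has been seen), and
classifies the accumulated adapter on first detection; the samples
consumed before the decision proxy the rejection latency.

`decide()` implements dynamic thresholds: a classified read is rejected
iff its barcode *leads* the tally (adapters, reads, or bases - the three
balancing strategies) by more than `slack` (default 1.2) times the largest
tally among the other barcodes already seen; tallies update after the
decision, so the threshold is recomputed continuously. Trimming the
current leader, rather than comparing against the mean of all seen
barcodes, keeps the rule robust to stray labels with token tallies that
occasional misclassifications produce - a mean-based threshold is dragged
down by such strays until it fires on every active barcode. Unclassified, noise and QC-failed reads are
always accepted: the balancer cannot act on an unknown identity, and this
conservative default means misclassification can never silently discard a
sample. Adapter-only molecules (unligated adapters, emulated at 5%) are
counted as adapters but produce no read output, and the read/base tallies
are corrected against that output.

`run_balancing_experiment()` replays a dataset under a fixed
sequencing-time budget where rejection frees the channel after the
consumed samples plus a 0.5 s penalty (voltage-flip and clearance proxy),
while acceptance occupies the channel for the full read. Balanced and
control runs under a matched seed and budget are compared by the Gini
coefficient over per-barcode read counts,
$G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar{x})$, and by the enrichment of
the least abundant barcode.

## Problem sizes and determinism

The reference conditions used by the whole-pipeline tests and the
acceptance script: 12 designed barcodes (600-candidate pool, search budget
1500 proposals per target - the design is budget-controlled and a larger
budget only tightens target matching), 450 reads per barcode in the
training pool with an 18% corrupted share (a noise-rich pool, so that 400
robust-Z outliers exist to mine), 400 + 400-noise training set, 200 clean
test reads per barcode at confidence cutoff 0.5, and a 10:1 two-barcode
skew replayed 100 times for the balancing comparison. Every stochastic
step takes an explicit seed; fixed seeds make reads, training and
predictions bit-reproducible.

## Limitations

* The synthetic k-mer model and squiggle generator do not emulate real
  pore chemistry; accuracy numbers on synthetic data characterize the
  pipeline, not expected field performance.
* The boundary detector is a single LLR/plateau method; it does not
  reproduce learned adapter detectors for newer chemistries.
* Barcode design optimizes predicted-signal separation; physical
  synthesis constraints (GC content, secondary structure) are not
  modeled.
* The balancer simulates channel time coarsely (no pore blocking, no
  channel death); its comparisons are qualitative.
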