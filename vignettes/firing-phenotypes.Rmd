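---
title: "From fluorescence movies to firing phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fluorescence movies to firing phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caltrace)
```

## The problem

Wide-field calcium imaging of cultured neurons (for example stem-cell-derived
cultures loaded with a fluorescent calcium indicator) produces a single-channel
movie in which each firing neuron appears as a bright soma whose fluorescence
transiently rises with every action potential and decays back over about a
second. `caltrace` turns such movies — or pre-extracted per-soma traces — into
per-neuron firing statistics and a population-level classification into
low-firing (LF), intermediate-firing (IF) and high-firing (HF) phenotypes.

The pipeline has six stages, each exposed as ordinary functions and tied
together by `run_pipeline()`:

1. **simulate** — synthetic ground-truth recordings (for testing and benchmarks);
2. **process** — ROI traces to ΔF/F₀ (%): smoothing, drift correction, normalization;
3. **screen** — supervised active/inactive classification of traces;
4. **infer** — spike inference by the peeling algorithm;
5. **features** — nine firing/bursting features per neuron;
6. **cluster** — PCA, k-means into 8 groups, group→class mapping.

## Trace processing

A soma is a square ROI (default 7 px, odd so a centre pixel exists); its raw
trace F\*(t) is the arithmetic mean of the ROI's pixels at each frame. The
default acquisition geometry is 960×720 px at 20 frames/s and 4.40 µm/px, so
the field of view is `fov_extent(960, 4.40)` = 4.224 ≈ 4.2 mm by
`fov_extent(720, 4.40)` = 3.168 ≈ 3.2 mm. (Note that a 7-px square at this
pitch covers (7·4.40)² ≈ 948 µm², not the ~645 µm² sometimes quoted for
soma-sized ROIs; the package follows the 7-px definition.)

Processing applies, in order:

* **Moving average**, 5 frames (250 ms at 20 FPS), centred. At the edges the
  window shrinks symmetrically instead of padding, so no values are invented
  and the length is preserved.
* **Block-spline drift correction**: the trace is cut into 25-s blocks, each
  block's mean is attached to its centre time, a natural cubic spline through
  these knots is evaluated at every frame and subtracted, and the spline's
  mean is added back. Constant traces are unchanged; the trace mean (and hence
  the baseline F₀) is preserved exactly; drift slower than roughly the block
  scale (the synthetic default is a linear trend plus a sinusoid of period
  ≥ 100 s) is removed, while 1-s transients pass through with their
  amplitudes preserved to within a few percent. The natural boundary
  condition makes the extrapolation beyond the outer block centres linear,
  which is exact for linear trends. A "smoothed-spline" order is not uniquely
  determined by this construction; cubic interpolation through block-centre
  knots is the package's choice.
* **ΔF/F₀**: F₀ is estimated as the 10th percentile of the drift-corrected
  trace — the estimator itself is a design choice; a low percentile is robust
  against sparse positive transients that occupy well under half of the
  recording — and traces are normalized as 100·(F\* − F₀)/F₀ (%). A
  non-positive F₀ raises an error rather than producing unusable traces.

ROI detection (`detect_rois()`) takes local brightness maxima of a time
projection above a user threshold (the threshold has no principled default;
it is data-dependent), accepted greedily in decreasing brightness under a
minimum-separation constraint, with exact ties broken in row-major order so
results are deterministic.

## Active/inactive screen

Traces are summarized by five shape features built from their intervals of
high activity (maximal runs above a threshold; default threshold 2× the
robust noise SD, 1.4826·MAD): fraction of time above threshold, number of
intervals, mean interval duration, maximum ΔF/F₀ and trace SD. A discrete
AdaBoost ensemble of depth-1 stumps (50 rounds by default) is trained on a
labelled subset — in production a manually curated label CSV, in tests and
simulations the generator's ground truth — and applied to the rest. A zero
vote margin classifies as *active*: ties are measure-zero and the choice
favours sensitivity. The exact feature set behind the original screening
step is not documented anywhere authoritative; this five-feature
reconstruction is deliberately simple and is validated by recovery
simulations (held-out accuracy and recovered active fractions) rather than
by correspondence to a reference implementation.

## Peeling spike inference

The single-spike calcium response is modelled as an instantaneous rise of
amplitude *A* (% ΔF/F₀) followed by exponential decay with time constant
τ = 1 s; events are detected above a threshold of 0.8 % ΔF/F₀. Peeling
iterates:

1. find the earliest event in the residual with a Schmitt trigger — arm when
   the signal rises above the threshold, release when it falls below half the
   threshold, require at least 2 frames armed (events truncated by the end of
   the trace are kept);
2. register a spike at the event-onset frame;
3. subtract the template from the residual and re-scan from the onset.

Iteration stops when no event remains, or at `max_iterations` (default
10× the frame count) with a warning and the partial train. Spike times are
frame-quantized (no sub-frame interpolation); at most one spike is registered
per frame, so perfectly coincident spikes are counted once. The template
amplitude defaults to 1.0 % ΔF/F₀ and can be calibrated per trace from the
median peak height of isolated supra-threshold events (`calibrate = TRUE`);
only the detection threshold, not the template amplitude, is fixed by the
method description, so the amplitude is an explicit, configurable model
parameter and the synthetic generator uses the same value by default. Only
single-spike templates are used; multi-spike template variants of peeling
are out of scope. The trigger constants (release at threshold/2, 2-frame
minimum duration) follow common peeling practice and are configurable.

On noiseless synthetic traces every spike with amplitude ≥ threshold and
inter-spike interval > 2 frames is recovered within ±1 frame and
`reconstruct()` of the inferred train reproduces the input to < 10⁻⁶; with
Gaussian noise at SD = A/8 the hit rate stays above 0.9 with fewer than 0.1
false positives per 10 s (these are the test-suite conditions).

## Firing and bursting features

Nine per-neuron features are computed from the spike train: number of spikes
(NS); firing rate (FR = NS/duration, Hz); mean and SD of the inter-spike
interval (ISI, s); number of bursts (B), a burst being a maximal run of ≥ 2
consecutive spikes whose gaps are all *strictly* smaller than 1 s (spikes
exactly 1 s apart do not concatenate); mean spikes per burst; mean
intra-burst ISI; mean inter-burst interval (IBI, start-to-start, s); and mean
burst length (s). Choices the burst rule leaves open: a minimum burst size
of 2 (a one-spike "burst" is meaningless under a concatenation rule), the
start-to-start IBI convention, and per-neuron (not population) ISI SD.
Undefined features (burst statistics when B = 0, ISI statistics when NS < 2,
IBI when B < 2) are `NA` and are excluded feature-wise from group summaries;
summaries report the sample mean, SD with the n−1 denominator, and
SEM = SD/√n.

## PCA, k-means and the LF/IF/HF map

Feature vectors are imputed per feature with the median (undefined values
only), z-scored — without standardization the spike count NS would dominate
every component simply by scale — and decomposed by PCA. Component signs are
fixed so the largest-magnitude loading is positive, making contribution
tables (100·loading²/Σloading²) reproducible. k-means (Lloyd, best of 50
random restarts, seeded) partitions the neurons in the full PC space into
k = 8 groups; k = 8 is the conventional group count for this kind of
phenotype segregation and is taken as given, with a config override but no
model-selection criterion.

Groups are mapped to classes from their medians: HF when median B ≥ 40 (per
10-min window) or median IBI ≤ 16 s; LF when median B ≤ 7 or median
IBI > 60 s; IF otherwise; burst counts are rescaled to the 10-min reference
window when recordings are shorter. The LF bound of 60 s deserves a note:
the narrative phenotype descriptions give LF "intervals greater than 40 s"
but simultaneously give IF an IBI range of 27–60 s, so the region 40–60 s is
ambiguous between the two; an IF population with a typical 12 bursts per
10 min has mean IBI near 50 s and would be swallowed by a 40-s LF rule. The
package therefore places the LF IBI bound at the upper edge of the IF range,
where the descriptions stop overlapping. A group in which no neuron bursts
cannot be mapped by these rules and falls back to spike-count tertiles of
the population. All thresholds are configurable
(`class_thresholds()`).

Short recordings deserve caution beyond the burst-count rescaling: IBIs
longer than the recording are censored, so LF neurons (typical IBI in the
minutes) need the full 10-min window for their IBI medians to mean anything.
The bundled demo config keeps the 10-min duration for exactly this reason.

## The synthetic generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated. Each phenotype is described by a tonic
background Poisson rate and a burst process: burst onsets Poisson with a
fixed expected count per 10-min window, spikes per burst 2 + Poisson(µ − 2),
intra-burst ISIs exponential truncated to [0.1, 1) s. The upper truncation
makes simulated bursts consistent with the 1-s burst rule; the 0.1-s floor
(2 frames at 20 FPS) keeps consecutive spikes resolvable on the frame grid
and plays the role of a refractory period. Defaults per 10 min: LF 4 bursts
(background 0.02 Hz), IF 12 bursts (0.05 Hz), HF 50 bursts (0.10 Hz,
intra-burst ISI 0.3 s) — chosen once from the reported phenotype ranges
(LF 1–7 bursts, IF 7–17 with IBI 27–60 s, HF 40–60 with IBI 10–16 s);
"inactive" cells fire nothing.

Traces follow the forward model
F\*(t) = baseline·(1 + (A/100)·Σᵢ e^−(t−tᵢ)/τ·1[t ≥ tᵢ]) + drift(t) + noise,
with baseline 100 a.u., A = 1.0 %, τ = 1 s, additive white Gaussian noise of
SD 0.125 a.u. (A/8 on the ΔF/F₀ scale — the shot-noise-dominated wide-field
regime the robustness tests assume) and a default drift of a slow linear
trend plus a 300-s sinusoid. No indicator chemistry, buffering, saturation
or bleaching is modelled, and noise is white rather than photon-count
distributed: passing tests demonstrate the pipeline's correctness under its
own model assumptions, not fidelity to any particular optical setup, whose
amplitude and noise statistics were never published. Movies render each soma
as a radially peaked blob over its ROI whose ROI-average equals the trace
exactly, on a constant background, stored as unsigned 16-bit TIFF; the
desk-scale default for movie tests is 128×128 px for 2 min rather than the
full 960×720 × 10 min, with the full geometry available through
configuration.

## Numerical and reproducibility choices

* All randomness flows from one seed; per-neuron and per-stage seeds are
  derived from it (`sample.int` under the master seed) and recorded in the
  run manifest, so a run is reconstructible from its manifest alone.
* Exponential templates are truncated where they fall below 10⁻⁸ of their
  amplitude, keeping noiseless round-trip residuals well under the 10⁻⁶
  test tolerance.
* The peeling scan is implemented in C++ (Rcpp) for speed; the test suite
  cross-checks it against a plain-R reference scan on noisy inputs.
* Problem sizes used by the validation suite are chosen for desk-scale runs:
  population recovery uses 1000 neurons × 10 min per seed; an experiment-scale
  analysis of ~10 000 neurons is a straightforward scale-up of the same code.
* Degenerate inputs fail loudly with typed conditions (`caltrace_param_error`,
  `caltrace_config_error`, `caltrace_dependency_error`, ...), and the config
  validator rejects unknown keys before any stage runs.

## Known limitations

* The screen's feature set and the exact "smoothed spline" are
  reconstructions of under-specified steps; both are validated by behaviour
  (recovery, invariance) rather than reference output.
* Class mapping assumes ~10-min recordings; shorter recordings censor IBI.
* No motion correction, neuropil subtraction or segmentation beyond square
  ROIs; recordings are assumed stationary.
* k = 8 is conventional, not selected by any criterion; the LF/IF/HF map is
  threshold-based, not learned.
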