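---
title: "Redundancy reduction for pressure sensor strips: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redundancy reduction for pressure sensor strips: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorprune)
```

## The model and its assumptions

A dense strip of pressure sensors inside a prosthetic socket produces one
synchronized kPa time series per sensor. The working assumption of the
whole method is that *redundancy shows up as similarity of the pressure
curves*: sensors loaded by the same anatomical region during gait trace
almost the same curve, so an unsupervised partition of the sensors by
curve similarity identifies groups within which most sensors can be
removed. The method is a four-step pipeline:

1. **Data input.** Readings are converted to kPa, clamped into the device
   reading range, and sliced into consecutive non-overlapping frames long
   enough to hold several gait cycles (default 500 samples = 5 s at
   100 Hz). Several cycles per frame matter: a frame shorter than a cycle
   would cluster sensors by instantaneous level rather than by gait
   morphology.
2. **Redundancy detection.** Each frame is clustered independently with a
   self-organizing map; the modal partition across frames is the
   redundancy-detection model. Voting across frames is what buys
   robustness: the SOM is sensitive to its random initialization, but an
   accidental split in one frame is outvoted by the other frames.
   K-means (with K fixed to the model's cluster count) is run on the same
   frames as a cross-check, and the model records on how many frames it
   agrees.
3. **Sensor density reduction.** Within each cluster of m sensors, all
   C(m,k) subsets of the k sensors to keep are scored by the Pearson
   correlation between the subset centroid and the full-cluster centroid,
   averaged over frames; the best subset wins. k is a user (prosthetist)
   decision, not an inferred quantity.
4. **Result validation.** On the whole recording, each cluster's pooled
   pressure histogram is compared with its kept subset's histogram by
   Jensen–Shannon divergence, together with the minimum JSD attainable by
   any k-subset and the relative change of mean pressure. The report
   prints the gaps; accept/reject is left to the reader, since the
   original account's thresholds ("gap < 0.06 insignificant", "< 0.1
   relatively low") are narrative judgments, not part of the algorithm.

## SOM details and the choice of σ₀

One sensor's in-frame series (length n) is one input vector — raw kPa,
not standardized, because all sensors share one physical unit and one
device range, and amplitude differences are themselves informative.
Weights connect the n input neurons to a 3×3 output grid (k = 9 neurons,
an upper bound of nine clusters for a ten-sensor strip). Training runs
τ = 10 epochs; in epoch t (0-based) each input in turn finds its best
matching unit (BMU; minimal Euclidean distance, ties to the lowest neuron
index) and every neuron j moves by

Δw = η(t) · exp(−D²/2σ(t)²) · (x − w),   σ(t) = σ₀e^(−t/τ),   η(t) = η₀e^(−t/τ)

with D the Euclidean distance between j and the BMU on the grid and
η₀ = 0.2. A cluster is the set of sensors sharing a BMU after training;
output neurons that win nothing simply contribute no cluster.

Defaults that the original account leaves unstated had to be fixed here:

* **Decay per epoch, not per sample.** τ = 10 with per-sample decay would
  collapse η after a single epoch; one iteration = one full pass over the
  inputs.
* **Weight initialization** is uniform within each input dimension's
  observed min–max. At kPa scale this puts the initial map inside the
  data cloud, which a 10-epoch budget needs. (Near-zero "small random"
  initialization behaves identically in our experiments once σ₀ is set as
  below.)
* **σ₀ = 0.5, half the grid spacing.** This is the one place we deviate
  from the common SOM convention σ₀ ≈ max(grid)/2. The convention is
  designed for topographic mapping, where neighboring neurons *should*
  end up interpolating inside a data cluster. Here the cluster
  *definition* is BMU-sharing, so the method needs the opposite regime:
  at most one neuron may converge into the interior of each redundancy
  group, otherwise the group fragments across two nearly identical
  prototypes. Empirically (10 seeds × 6 frames of the synthetic fixture,
  noise 0–8 kPa): with σ₀ ≥ 1.0 the seven-sensor group splits in every
  seed — even noise-free, because per-sensor gain and saturation spread
  the group — while any σ₀ ≤ 0.8 recovers the planted two-group structure
  in 10/10 seeds at every noise level. We set σ₀ = 0.5, mid-regime, so
  the conclusion does not sit on the 0.8/1.0 boundary. With this narrow
  neighborhood the SOM behaves as winner-take-most vector quantization
  with weak lateral coupling, which is exactly what partition-by-BMU
  requires.
* **Determinism.** BMU ties break to the lowest neuron index; inputs are
  presented in column order by default (`"shuffled"` is available for
  stability studies); frame i of a consensus run uses seed + i − 1.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `frame_length` | 500 | samples | 5 s at 100 Hz ≈ 4–5 gait cycles; 250 is offered for sensitivity reports |
| `grid_rows × grid_cols` | 3×3 | neurons | upper bound of 9 clusters for a 10-sensor strip |
| `eta0` | 0.2 | – | reference learning rate |
| `sigma0` | 0.5 | grid units | see above |
| `tau` | 10 | epochs | reference iteration budget |
| `kmeans iterations` | 10 | rounds | reference cross-check budget |
| `k` | per cluster | sensors | a clinical choice, never inferred |
| `n_bins` | 64 | bins | one bin per kPa over the 0–64 kPa range |

## Numerical choices

* **PCC** is computed as Σ(x−x̄)(y−ȳ)/√(Σ(x−x̄)² · Σ(y−ȳ)²) and clamped
  into [−1, 1] against round-off. A zero-variance series (a sensor
  saturated flat for a whole frame — a real occurrence) raises an
  explicit error; `select_k()` converts it into a per-frame exclusion
  with a warning, and a subset unscorable in every frame can never be
  chosen. Nothing propagates NaN.
* **JSD** uses base-2 logarithms — the only base for which the stated
  [0, 1] bound holds (natural logs cap at ln 2) — with 0·log 0 := 0, and
  is clamped into [0, 1] against round-off.
* **Histograms** always span the device reading range, not the data
  min–max, so any two histograms from one recording share support; the
  last bin is closed so saturation mass lands in the top bin.
* **Tie-breaks** are all deterministic: modal-partition ties prefer fewer
  clusters (a coarser model detects more redundancy, the method's
  purpose) then the lexicographically smallest canonical form; PCC ties
  prefer the lexicographically smallest subset.
* **Framing** discards a trailing partial frame rather than padding — the
  reference geometries (3000/500, 3000/250) divide evenly, and discarding
  never fabricates data. Missing values are an error; gaps are out of
  scope.

## What the synthetic generator emulates — and what it does not

`simulate_recording()` produces, per redundancy group, a latent periodic
waveform: a raised, asymmetric stance pulse (a rectified sinusoid over
the stance fraction of the cycle, taken to a power so stance is peaky and
swing is flat; trough-to-trough = one gait cycle) at a configurable
cadence (default 0.9 cycles/s → 4–5 cycles per 5-s frame) with ±5 %
per-cycle period jitter. All groups share the same stride timing and
differ by phase, amplitude and baseline — as regions of one limb loading
at different moments of the same gait. Sensor s in group g reads
`clamp(gain_s · w_g(t) + ε, 0, 64)` with iid Gaussian ε.

Chosen-once calibration: noise sd 2 kPa and per-sensor gains U[0.9, 1.1]
put the within-cluster sensor-vs-centroid correlation near 0.99, matching
the reported behavior of real intra-socket strips, and the demo fixture's
second group (amplitude 75 kPa against the 64 kPa ceiling) saturates part
of the time, reproducing the top-bin mass that real recordings show.

The generator does **not** emulate shear coupling, limb-volume drift,
step-to-step amplitude variability, sensor crosstalk, or spatially
continuous pressure maps. A green recovery test therefore establishes
that the pipeline recovers *planted, stationary* group structure under
iid noise and saturation — not that it would segment any clinical
recording correctly.

## Known limitations

* A SOM partition is only as fine as BMU-sharing allows; borderline
  sensors sitting between two groups flip the modal partition at higher
  noise rather than receiving any uncertainty measure.
* Exhaustive C(m,k) search is the point (m ≤ 10 on a strip), but the cost
  grows combinatorially if the method is applied to hundreds of sensors.
* Consensus is exact-partition voting; no co-association/soft consensus.
* The frame-length comparison (`frame_length_report()`) reports support
  per length; it deliberately does not choose a frame length.
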