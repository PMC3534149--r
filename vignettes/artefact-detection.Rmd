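---
title: "Detecting and correcting spatial artefacts on probe grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting spatial artefacts on probe grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainr)
library(dplyr)
```

## The model

A microarray measurement is a lattice of probe intensities. Spatial
artefacts — typically stains from partial drying or uneven hybridization —
corrupt a contiguous region of probes with artificially high values. Robust
probeset summarization does not repair this: normalization reacts to the
distorted global intensity distribution, so even probesets far from the
stain shift, and probesets with several corrupted probes shift badly.

stainr's detection model is deliberately simple. Each probe `j` receives a
noise score

$$ s_j = \log_2 \frac{v_j + c}{v'_j + c}, $$

the log fold-change of its intensity $v_j$ against a control value $v'_j$,
with a pseudocount $c$ at the platform's detection limit. Three controls are
supported:

* an artefact-free **replicate** (loess-normalized first, so
  intensity-dependent bias does not masquerade as noise);
* the per-probe **median across replicates** when no single clean replicate
  can be nominated;
* the **biological control** of metabolic-labeling designs: total RNA (`T`)
  splits into newly transcribed (`N`) and pre-existing (`P`) fractions, so
  `T ≈ λ₁N + λ₂P` must hold per probe after scaling for the different RNA
  amounts. `fit_fraction_model()` estimates the nonnegative scalings by
  (nonnegative) least squares and `control_from_fractions()` produces
  $v' = λ_1 N + λ_2 P$.

Median-polish residuals (`residual_noise_scores()`) form a fourth channel:
probes whose measurements the additive probeset model cannot reconcile with
the other arrays earn large absolute residuals.

Detection applies a strict threshold, $s_j > t$. The **window criterion**
first replaces each score by a distance-weighted average over the
$(2k+1)\times(2k+1)$ window centered on the probe,

$$ sw_j = \frac{\sum_{p} s_p\, w(p,j)}{\sum_{p} w(p,j)}, \qquad
   w(p,j) = \begin{cases} 2 & p = j\\ 1/d(p,j) & p \ne j, \end{cases} $$

with Euclidean distance on the lattice and the window truncated at the
borders. Because artefacts are spatially coherent while isolated noisy
probes are not, smoothing suppresses lone outliers and fills in
under-scored probes inside the stain, which is what makes a single
threshold separate stain from background.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 16 | detection limit added to both intensities before the log ratio; platform-dependent, keeps zero intensities finite and shrinks fold-changes of probes below the detection limit |
| `k` | 25 | window half-width in probes; the window should sit well inside the artefact scale — for stains much smaller than `2k+1` the smoothed peak is diluted |
| `self_weight` | 2 | weight of the center probe relative to `1/d` neighbors |
| `t` | — | detection threshold; chosen manually from probe noise plots, replicate scatter plots and `threshold_table()`. `suggest_threshold()` (99.9th score percentile) is a convenience starting point only |
| `mu_log2`, `sigma_log2` | `log2(850)`, 1 | log2-scale location/spread of planted artefact intensities, matching intensities observed inside real stains |
| `delta` | — | per-probe corruption probability for random spiking |

The log-normal spike distribution is interpreted on the log2 scale
(`value = 2^z`, `z ~ Normal(log2(850), 1)`); pass converted parameters if a
natural-log reading is wanted.

## Correction

`correct_by_probeset_mean()` replaces each flagged probe by the arithmetic
mean of its probeset's unflagged intensities *on the same array*, so
between-array intensity differences never enter. When every probe of a
probeset is flagged, no meaningful estimate exists: all its probes are set
to 0, the probeset summarizes to the floor value, and the ids are reported
(exclude them downstream). `filter_probesets()` instead removes flagged
probes from the membership table and emits a kill list; probesets that lose
all probes are dropped and reported rather than silently zeroed. Probes
flagged but absent from the map (controls, background features) are left
untouched by both routes. Corrected grids round-trip through text CEL files
so standard pipelines consume them unchanged.

## What the simulator emulates — and what it does not

`generate_baseline_arrays()` draws one true log2 intensity per probe from
`Normal(8, 2)` shared across replicates, adds independent `Normal(0, 0.25)`
log2 replicate noise, and tiles probes into scattered probesets of four
(members sit far apart on the lattice, never adjacent, as on real arrays).
These values give a realistic dynamic range (about 5 log2 units between the
1st and 99th percentile) and replicate scatter comparable to good-quality
arrays. Stains are planted either probe-wise (`random_spike()`), as a dense
disc with a sparse halo (`stain_mask()` + `spike_stain()` — the geometry of
a drying artefact: a saturated core and a diffuse rim), or by projecting a
stain from a denser onto a coarser lattice (`project_artefact()`: block
maxima, rescaled by the arrays' 75th-percentile ratio).

The simulator does **not** model probe-sequence effects (GC affinity),
intensity-dependent replicate variance, spatial intensity gradients outside
the stain, or optical blooming at stain edges. Passing benchmarks on these
simulations therefore demonstrates that the estimators and the detection
geometry behave as designed, not that any particular threshold transfers to
a given real platform — thresholds remain a manual, plot-guided choice.

## Numerical choices

* **Quantile normalization** maps every array onto the mean of the sorted
  intensity vectors; tied values receive the mean of the reference
  quantiles over their tied ranks (symmetric and order-independent).
* **Loess normalization** fits `M ~ A` locally linearly with span 2/3 and a
  robust (symmetric) family, three total iterations, so a stain occupying a
  few percent of probes does not drag the trend. Above 50,000 probes the fit
  uses an A-stratified deterministic subsample (every k-th probe in A
  order) and interpolates; predictions outside the fitted A range are
  clamped to its ends. An exactly constant `M` is returned as its own
  trend, since zero residuals leave robust reweighting undefined.
* **Window smoothing** is computed as two translation-invariant
  convolutions — kernel ⊛ scores and kernel ⊛ ones — whose ratio reproduces
  border truncation exactly. The FFT route is used when the kernel fits
  inside the grid; otherwise a direct shifted accumulation. Both agree with
  the naive double loop to well below 1e-9; the naive loop is kept in the
  test suite as the oracle.
* **Median polish** sweeps rows first, then columns, for at most 10
  iterations, stopping when the total absolute residual changes by less
  than 0.01. Only the chip effect (overall + column) and the residuals are
  part of the public contract; row/column effects are reported as the sweep
  order produces them. Intensities enter as `log2(v + c)` with the
  detection-limit pseudocount, so zeroed probes stay finite.
* **Fraction model**: the unconstrained least-squares solution is used when
  it is already nonnegative; otherwise nonnegative least squares. Collinear
  `N`, `P` raise a rank error.
* **PR curves** place one point per distinct score value (ties enter
  together, no intra-tie interpolation); `precision_at_recall()` reads the
  highest threshold whose recall reaches the target.
* `probe_id = y * n_cols + x + 1` (1-based, row-major over 0-based
  coordinates) everywhere; all APIs exchange `(x, y)` pairs to avoid silent
  transposition.

## Design decisions taken where the design was open

* Replicate fold-change scoring applies **loess pair normalization only**
  (no quantile step) before the scores: quantile normalization reacts to
  the stain itself and would contaminate the control.
* Detection defaults to **absolute** fold-changes; signed scores are kept
  for diagnostic plots, where the diverging colormap is centered on zero.
* There is **no automatic threshold selection**; the package reports
  flagged-count-versus-threshold tables instead, and labels the quantile
  default as a convenience.
* Mean replacement uses **all probes present in the map** of a probeset,
  not only core probes; kill lists and replacement skip unmapped probes.
* Blocks at odd grid edges during stain projection are truncated blocks
  (max over available probes).

## Benchmark scales

The shipped benchmarks run at sizes a laptop handles in minutes: the stain
detection benchmark (`benchmark_stain_detection()`) uses ten seeded
simulations of three 300×300 replicates with a ~2% disc-plus-halo stain and
`k = 25`; the spike-count experiment pools twenty seeded 80×80 runs at
δ = 0.05; the correction demonstration plants a disc covering ~15% of a
60×60 grid. That last scenario deliberately models a *substantial* artefact:
with a ~2% stain the probeset MAD between replicates is dominated by
replicate noise and median polish already absorbs single corrupted probes,
so correction has nothing measurable to repair; the correction methods
exist for heavily stained arrays, where many probesets lose two or more
probes and the normalization distortion is real. On such arrays both
correction routes reduce the mean absolute deviation from the replicate
diagonal in every seeded run.

## Known limitations

* Binary (Calvin/Command-Console) CEL dialects are not written; text
  version-3 CEL is the reference dialect with a byte-identical round trip.
  MEAN values are emitted at one-decimal precision.
* Mean replacement estimates a corrupted probe by its probeset's survivor
  mean on the raw scale; when probe affinities within a probeset span
  orders of magnitude this is a coarse estimate, and the filtering route is
  preferable.
* The window kernel is isotropic with unit grid spacing; anisotropic
  feature geometries and multi-scale windows are out of scope.
* Residual scores from median polish differ numerically from robust
  M-estimation probe-level models; agreement between the channels is
  qualitative (both rank a planted outlier first), not numeric.
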