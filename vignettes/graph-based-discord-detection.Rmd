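---
title: "Graph-based subsequence anomaly detection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based subsequence anomaly detection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsgraph)
```

## The model

A subsequence anomaly is a contiguous stretch of a series whose *waveform*
deviates from the series' recurring patterns. The detector in this package
rests on one assumption: **normal waveforms recur many times, anomalous
ones rarely**. It makes that assumption operational in three stages.

**Stage 1 — embedding.** Every length-`w_g` sliding window (step 1) is
z-normalized to zero mean and unit population standard deviation, so
comparison is shape-based, not level-based; the whole row set is then
projected onto its top two principal components. Windows with similar shapes
land near each other in this 2D spatial-temporal space, and the series
becomes a temporally ordered trajectory through it. For a quasi-periodic
signal the normal cycle traces a dense closed loop; an anomalous waveform
detours off the loop.

**Stage 2 — graph.** The bounding box of the embedded points is divided
into an `n_c × n_c` grid; each occupied cell is a node, and each consecutive
window pair increments the weight of the directed edge between its cells
(a self-loop when both fall in one cell). Edge weights therefore count how
often the series repeats each shape transition. Two properties follow
exactly and are enforced by tests: total edge weight equals `N − 1`
(one transition per window pair), and the node count never exceeds
`n_cell = n_c²` regardless of series length — the representation's size is
bounded by a constant, which is what makes it cheap on long recordings.

**Stage 3 — scoring.** The windows map the series to a node path
`P_T = ⟨v⁰, …, v^{N−1}⟩`. A length-`ℓ` subsequence starting at `i` is scored
by the mean weight of the `ℓ` edges its path traverses:

$$\mathrm{score}(i) = \frac{1}{\ell}\sum_{k=i}^{i+\ell-1} w(v^k, v^{k+1}).$$

Because the weights are *global* occurrence counts, a rare waveform scores
low whether it occurs once or several identical times — the property that
distinguishes this detector from nearest-neighbor discord definitions,
which are defeated by recurring anomalies (each instance finds its twin).
The profile is smoothed with a centered moving average and the lowest
minima are reported under exclusion zones.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `w_g` | samples | — (user; `period − 20` advised) | embedding window; should sit slightly *below* the normal-pattern length so one window spans most of one cycle without straddling two |
| `l` | samples | `w_g` | scored subsequence length; the method is deliberately robust to mismatch with the true anomaly length |
| `n_cell` | cells | 100 | grid resolution; too coarse merges normal and abnormal trajectories, finer than ~100 changes little but grows the graph |
| `smooth_window` | samples | `w_g` | moving-average width; aligns scores of heavily overlapping subsequences |
| `k` | count | `NULL` | detections to report; `NULL` returns the full ranked list, so choosing `k` is not required |

`estimate_period_hint()` suggests the normal-pattern length as the lag of
the highest *local* autocorrelation peak (lag ≥ 2); the raw maximum is
useless here because any smooth signal has enormous autocorrelation at tiny
lags. A weak peak (< 0.3 by default) is flagged unreliable rather than
returned silently.

## Numerical and convention choices

These points are where more than one reasonable convention exists; the
package fixes each one deterministically.

- **Path-span of a scored subsequence.** The formal score above has `ℓ`
  edge terms over `ℓ + 1` path nodes, giving valid starts
  `i = 0 … N − ℓ − 1`; the package follows that exactly. (Equivalent
  listings that use `ℓ` nodes and `ℓ − 1` edges are off by one.)
- **Z-normalization** uses the population (divisor-`n`) standard deviation,
  the common convention in time-series discord work. Windows whose sd falls
  below `1e-12` become all-zero rows rather than errors, so constant
  segments flow through the pipeline; their indices are reported.
- **PCA determinism.** The projection is computed by exact
  eigen-decomposition of the `w_g × w_g` covariance (no randomized solver),
  and each component's sign is fixed by making its largest-magnitude loading
  positive. PCA is sign-ambiguous and the grid binning downstream depends on
  orientation, so *some* fixed convention is required; this one is as good
  as any and bit-reproducible. Centering uses the column means of the
  normalized matrix, the default of every mainstream implementation.
- **Grid binning.** Points exactly on the right/top boundary clamp into the
  last cell (every point must get a cell); a degenerate axis (all
  coordinates equal) maps everything to column/row 0. Node ids are row-major
  over the full grid so names are stable across runs.
- **Smoothing** is centered, with symmetric shrinkage at the boundaries
  (no invented padding values); this keeps score minima aligned with
  anomaly centers. An even width is widened to the next odd width.
- **Ranking ties** break toward the smaller start index, so output is
  deterministic end to end; the whole pipeline contains no randomness.
- **Cross-length merge.** How detections at different scanned lengths should
  be combined is genuinely open. Since scores are per-edge means they are
  comparable across lengths, so the merged list pools all per-length
  detections, sorts by ascending score, and greedily keeps entries whose
  *flagged data spans* do not overlap. The flagged span of a detection at
  start `i` with length `l` is `[i, i + l + w_g)` — the samples covered by
  the windows its path scores. Merging on bare intervals `[i, i + l)`
  instead lets one long anomaly reappear as several short disjoint
  detections, which is the trivial-match problem at the cross-length level.
  For the same geometric reason, `evaluate_topk(..., pad = w_g)` judges
  scan detections by their flagged span: at `l < w_g` a detection's bare
  interval can sit entirely ahead of the anomaly whose windows it scores.
- **Degenerate inputs.** NaN/Inf in input is a hard error naming the line
  (no imputation semantics exist for the method); series shorter than 2
  points, windows outside `[2, n − 1]`, and non-square `n_cell` are
  rejected at the door.

## The synthetic generator

`synth_series()` emulates the structure the detector exploits in its target
data — long quasi-periodic biosignals: a waveform template (`pqrst`, an
ECG-like sum of fixed Gaussian bumps; `sine`; `square_smooth`) tiled for
`n_cycles` cycles, additive Gaussian noise, and planted anomalous waveforms
(`widened`, `inverted`, `premature` — parameterized distortions mirroring
PVC-like morphology). Anomaly waveforms are deterministic functions of
`(shape, length, amplitude)`, so planting one shape several times creates
*exact twins* before noise: the recurrent configuration.

Each cycle is drawn with small random amplitude (sd 5%), timing (sd 0.5
samples at period 100), and width (sd 2%) perturbations. This beat-to-beat
variability is universal in physiological recordings and is essential to a
faithful fixture: a strictly identical tiled cycle makes every normal window
match its neighbors to within noise, which hands the nearest-neighbor
baseline an unrealistic advantage structure (and makes z-normalization
amplify noise in low-variance anomaly windows). With realistic variability,
normal windows differ by alignment and shape residuals while twin anomalies
remain identical — the regime the twin-freak problem describes.

What the generator does **not** emulate: drifting baselines, heart-rate
trends, non-stationary noise, morphology changes over time, multichannel
structure, or physiologically accurate ECG dynamics. Passing tests on these
fixtures therefore demonstrate the method's mechanics — graph construction,
global scoring, recurrent-anomaly recovery, length robustness — not clinical
performance on real recordings.

## Test and measurement scale

The test suite and the acceptance script run the study conditions at
series of 5 000 samples (period 100 × 50 cycles, `w_g = 80`,
`n_cell = 100`, noise sd 0.02, 20 replicate seeds per measurement), with
structural properties additionally checked on random-walk series up to
5 000 samples and score oracles on paths up to 2 000 nodes. These sizes were
chosen so the entire suite runs in well under a minute while each
measurement still averages over 20 independent replicates; the method itself
has no practical size limit near this range (the graph is constant-size, and
all per-window work is linear or BLAS-bound).

## Limitations

- The normal-pattern length must still be supplied (or taken from the
  autocorrelation hint); a badly wrong `w_g` degrades the embedding.
- Scores are relative rankings, not calibrated probabilities; the package
  deliberately provides no hard anomaly/normal threshold.
- The graph is built from, and scores, one series; scoring new data against
  a frozen graph (streaming) is out of scope.
- Only univariate series are supported.
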