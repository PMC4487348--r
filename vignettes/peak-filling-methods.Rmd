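---
title: "Peak filling: how the baseline estimator works and how it was validated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak filling: how the baseline estimator works and how it was validated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakfill)
```

## The model

A measured spectrum is treated as

$$ y_i = b_i + \sum_k h_k \exp\!\left(-\tfrac{(i - c_k)^2}{2\sigma_k^2}\right) + \varepsilon_i, $$

a slowly varying baseline $b$, sparse approximately Gaussian peaks, and
additive noise. Peak filling estimates $b$ without modelling the peaks: it
exploits only the assumptions that (i) the baseline varies slowly relative to
the bucket width, (ii) peaks are sparse enough that most buckets contain some
channels at baseline level, and (iii) noise is roughly symmetric, so that a
smoothed spectrum crosses the baseline rather than riding above it.

The pipeline is the classic four-stage construction:

1. **Smoothing** by the Whittaker smoother,
   $z = \arg\min_z \lVert y - z\rVert^2 + \lambda \lVert \Delta^2 z \rVert^2$.
2. **Subsampling**: bucket minima of $z$.
3. **Suppression**: iterated, bidirectional, in-place
   $v_j \leftarrow \min(v_j, \text{mean of the window around } j)$ with a
   logarithmically shrinking window.
4. **Stretching**: interpolation from bucket centres back to all channels,
   followed (optionally) by **subtraction**.

## The four parameters

| parameter | units | default | role |
|---|---|---|---|
| `lambda` | log10 of the penalty | 4 | vertical placement: larger values flatten the smoothed spectrum so the baseline runs through the *middle* of the noise band; `NA` skips smoothing and the baseline settles at the *bottom* of the band. `0` (penalty $10^0$) is the conventional choice when the baseline should hug the spectra from below. |
| `bins` | buckets (count or explicit edges) | $n/10$ | flexibility: many narrow buckets follow steep or locally structured baselines but risk rising into peaks; few wide buckets give a rigid baseline that can detach under a concave baseline. Variable-width edges put flexibility only where it is needed. |
| `hwi` | buckets | none (required) | initial suppression window half-width. About half the width of the widest peak, in buckets, so the window can "see across" a peak to baseline level on both sides. |
| `it` | iterations | 10 | suppression effort. Too few: the baseline rides into peak clusters. Too many, on concave baselines: over-suppression ("detaching"). |

The window schedule interpolates $\log_{10}$-linearly from `hwi` down to 1:
`window_schedule(15, 20)` gives
`r paste(window_schedule(15, 20), collapse = " ")`. The half-width is updated
after each completed right-and-left pair of sweeps, and the final iteration
always works at ±1 when `it >= 2`. A rounding guard
(`ceiling(round(10^d, 9))`) keeps floating-point excess in `10^log10(hwi)`
from inflating the first half-width by one.

## Numerical choices

* **Whittaker solve.** The stationarity system $(I + \lambda D^\top D)z = y$
  is banded SPD and solved by sparse Cholesky with up to two iterative
  refinement steps, which hold the relative stationarity residual near
  machine precision for the penalties used in practice. For extreme penalties
  ($\lambda > 10^8$) the normal equations have condition $\sim 16\lambda$ and
  lose many digits, so the solver switches to sparse QR on the augmented
  least-squares system $[\,I;\ \sqrt{\lambda}D\,]z \approx [\,y;\ 0\,]$,
  whose condition is only $\sim\sqrt{\lambda}$. That path is slower and only
  matters when deliberately driving the smoother to its straight-line limit.
* **Bucket layout.** For a count $b$, the base width is
  $\lfloor n/b \rfloor$ and the remainder channels widen the *trailing*
  buckets by one channel each — deterministic and order-independent. Bucket
  centres are midpoints of the index range (possibly half-integral). All
  user-facing indices are 1-based inclusive, the R convention.
* **End handling.** During suppression the window shrinks symmetrically near
  the ends (`a = min(hwi, distance to nearest end)`), keeping it centred so a
  steep baseline at the spectrum edge is not dragged down. During stretching,
  channels outside the first/last bucket centre take the terminal knot value;
  constant extension avoids extrapolation artifacts on steep ends.
* **In-sweep updates.** The window mean uses the vector *as it currently is*,
  including values updated moments earlier in the same sweep. This speeds
  convergence and is the reason a single left-to-right sweep is biased —
  hence the mandatory return sweep.
* **"Constrained smoothing splines".** The spline stretching mode is realised
  as the Fritsch–Carlson shape-preserving cubic Hermite interpolant
  (`stats::splinefun(method = "monoH.FC")`): smooth, exact at the knots, and
  monotone between consecutive knots, so it can never overshoot beyond
  adjacent knot values — the property that matters when knots are minima.
  Other constrained-spline readings are possible; this one is deterministic
  and has no extra tuning parameter.
* **Degenerate inputs.** Spectra with fewer than $2 \times$ `bins` channels
  are rejected outright rather than silently re-binned; empty vectors,
  non-finite values, and non-increasing axes fail on load.

## The synthetic generator

Because real MALDI-TOF/LIBS reference spectra are not shipped, validation
rests on a generator whose truth is known exactly:
`spectrum = baseline + Gaussian peaks + N(0, noise_sigma)` with a stored
truth vector and a *peak-free mask* (channels farther than 4 peak-sigmas from
every peak centre; beyond 4σ the residual peak mass is negligible for scoring). Two
presets, frozen at design time, emulate the qualitative shapes of the two
motivating instrument families:

* **MALDI-like** (`maldi_like_preset()`): 4000 channels on an m/z axis, an
  exponentially decaying baseline ($120 e^{-4t} + 5$), 20 peaks of widths
  σ = 3–15 channels including an unresolved cluster of four wide peaks, and
  noise σ = 1.5 — small relative to peak heights (25–180), as in protein
  spectra. The standard parameters (`lambda = 4`, `bins = 400`, `it = 10`,
  `hwi = 6` buckets ≈ half the widest peak) recover the truth on peak-free
  channels with RMSE ≈ 1.3, comfortably inside the noise level.
* **LIBS-like** (`libs_like_preset()`): 1500 channels on a 300–600 nm axis, a
  tilted baseline with two localised dips (near 360 and 530 nm), one broad
  steep ridge (near 400 nm), 25 narrow emission lines (σ = 1.5–4 channels,
  heights 40–300), noise σ = 1. `libs_like_edges()` carries the hand-tuned
  variable bucket widths — 10 channels across the dips, 12 across the ridge,
  20 elsewhere — tuned by inspecting estimates on the preset, which is
  exactly the adjustment loop the method prescribes for such baselines.

For the LIBS scenario the package uses `lambda = 0`, window ±1 bucket and
`it = 2`. Heavier smoothing is counter-indicated there: emission lines two
orders of magnitude above the noise get smeared by a strong Whittaker pass
into precisely the narrow-bucket regions that must follow the dips, lifting
the estimate; conversely, more iterations over-suppress the ridge. With the
light-smoothing setting the estimate stays within ≈1.5σ RMSE of the truth on
peak-free channels across seeds.

What the generator deliberately does **not** simulate: detector saturation,
isotope envelopes, chemical (multiplicative/heteroscedastic) noise, peak
shape asymmetry, or axis warping between spectra. Passing the recovery tests
therefore demonstrates the estimator's behaviour under the stated model — a
smooth baseline under sparse symmetric peaks with additive Gaussian noise —
not robustness to every artifact of real instruments.

## Validation strategy and problem sizes

The test suite checks, besides the per-stage unit examples:

* **Hand-computed oracles** — e.g. two ±1 sweeps on `c(0,0,10,0,0)` give
  exactly `c(0, 0, 10/9, 0, 0)`, following the update rule by hand.
* **Invariants** on 100 seeded random spectra of up to 500 channels:
  suppression never raises any value (checked sweep by sweep); a constant
  spectrum is a fixed point of the whole pipeline; the pipeline is
  equivariant under $y \mapsto a y + c$, $a > 0$ (to $10^{-8}$ relative);
  the stretched baseline reproduces the suppressed values at every bucket
  centre (exactly for linear, to $10^{-10}$ for the spline); the Whittaker
  output satisfies its stationarity system to $10^{-8}\lVert y \rVert$ and
  never has a worse objective than $y$ itself.
* **Oracle equivalence**: deliberately naive loop re-implementations of
  subsampling and suppression agree *bitwise* with the production code on 50
  random vectors (length ≤ 500, `hwi` ≤ 20, `it` ≤ 10).
* **Recovery and centring**: the two presets above, plus a pure-noise
  spectrum (2000 channels, σ = 1) corrected with heavy smoothing
  (`lambda = 6`, chosen by the centring principle — a featureless spectrum
  warrants a near-rigid fit), whose corrected mean stays within ±0.2σ of
  zero.

These sizes keep the whole suite under a minute while exercising every code
path; the estimator itself is $O(n)$ in channels and routinely handles
full-resolution spectra.

## Known limitations

* The baseline is anchored at bucket *minima*, so with smoothing disabled it
  is biased low by roughly the expected minimum of the noise within a bucket
  (≈1.5σ for 10-channel buckets); enable smoothing when a noise-band-centred
  zero line matters.
* Suppression has no convergence-based early stop; `it` is a fixed budget.
* Bucket edges are shared across all spectra of a set, which assumes baseline
  features (e.g. LIBS dips) do not shift much between spectra.
* No peak detection, alignment, or alternative baseline methods are included.
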