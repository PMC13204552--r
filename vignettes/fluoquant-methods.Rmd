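---
title: "Quantifying fluorescence microscopy: colocalization, mitochondrial morphometry and JC-1 profiling with fluoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluoquant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoquant)
```

# Scope

`fluoquant` quantifies 2-D multi-channel fluorescence images of cultured
cells along three axes that recur in chemotherapy-stress studies of
glioblastoma cells: where a fluorescent drug such as doxorubicin
accumulates relative to organelle markers (colocalization), how the
mitochondrial network is shaped (morphometry), and how the mitochondrial
membrane potential is distributed along individual organelles (JC-1
ratiometric profiling). Every pipeline is deterministic: the same images
and configuration produce byte-identical output tables.

Images are treated as calibrated rasters: coordinates are (row, col),
1-based, with pixel centers at integer positions; intensities are carried
unchanged from the file (integer TIFF samples are never rescaled on
load, because acquisition-matched illumination makes raw intensities
comparable and any normalization is the analysis's job, not the
loader's). Physical lengths are converted to micrometers only at
measurement time via the mandatory `pixel_size_um` calibration — the
package deliberately has no default pixel size, since none can be
assumed for a given microscope/objective combination.

# Colocalization statistics

Two channels $A$ and $B$ are segmented independently: an Otsu threshold
over a 256-bin histogram spanning the observed min–max, strictly-greater
comparison (ties fall to background), followed by morphological closing
with a disc of radius 1 px (configurable) to seal small gaps. The union
of the two masks defines the pixel domain of the statistics.

* **Pixel-wise PCC**: the sample Pearson correlation of $(a_i, b_i)$
  over union-mask pixels. A constant channel leaves it undefined; the
  result is then reported as missing with a reason, never coerced to 0.
* **Scan-line PCC**: an "optimized scan line" is the full-image chord
  through the union-mask centroid whose orientation, among
  `n_orientations` (default 36) evenly spaced in $[0, \pi)$, maximizes
  the summed product of the two channels' intensities sampled along the
  chord (bilinear interpolation, 0.5 px steps, endpoint-inclusive). Ties
  break to the smallest orientation index, so the search is
  deterministic. This objective — maximal joint signal — is one
  reasonable formalization of an "optimized" profile line; because the
  criterion is a design choice, line-PCC values are comparable within a
  study analyzed by this package but not across tools that draw their
  lines differently.
* **Manders $M_1/M_2$** (thresholded variant): $M_1$ is the fraction of
  $A$'s integrated intensity over $A$'s own mask that falls inside $B$'s
  mask, and symmetrically for $M_2$. Each channel's own Otsu mask is its
  domain; the other channel's mask is the colocalization criterion.
* **ICQ**: with within-mask means $\bar a, \bar b$, the fraction of
  union-mask pixels with $(a-\bar a)(b-\bar b) > 0$ among pixels with a
  nonzero product, minus $0.5$; range $[-0.5, 0.5]$. Pixels with an
  exactly zero product are excluded from both numerator and denominator
  so that masked zeros cannot bias the quotient toward $-0.5$.

# Mitochondrial morphometry

The morphometry pipeline is: Frangi tubeness (scales $\sigma \in \{1, 2,
3, 4\}$ px) → one batch-global Otsu threshold → 8-connected components →
per-object skeleton length and aspect ratio → a closed-interval
1–20 µm length filter → per-condition summaries.

**Frangi tubeness.** At each scale the image is convolved with
Gaussian-derivative kernels (support $\pm\lceil 4\sigma \rceil$, the
second-derivative kernel normalized to zero sum so constant images have
an exactly zero Hessian); the scale-normalized Hessian eigenvalues
$|\lambda_1| \le |\lambda_2|$ give

$$V = \exp\!\left(-\frac{R_B^2}{2\beta^2}\right)\left(1 -
\exp\!\left(-\frac{S^2}{2\gamma^2}\right)\right),\qquad
R_B = \lambda_1/\lambda_2,\; S = \sqrt{\lambda_1^2 + \lambda_2^2},$$

zeroed where $\lambda_2 \ge 0$ (bright-ridge mode), maximized over
scales. $\beta = 0.5$; $\gamma$ defaults to half the maximum
structureness per image and scale, which makes the response independent
of bit depth and overall gain. A guard skips a scale when its maximal
structureness is numerically negligible relative to the image scale, so
FFT round-off on flat images cannot masquerade as structure.

**Global thresholding.** The Otsu threshold is computed once on the
pooled pixels of every tubeness map in the batch — all experimental
conditions together — and applied unchanged to each map. This preserves
genuine inter-condition differences that per-image thresholding would
equalize. The threshold is order- and split-invariant because only the
pooled histogram enters.

**Skeleton length.** Objects are thinned with the Guo–Hall
two-subiteration parallel algorithm to a 1-px, 8-connected skeleton.
Guo–Hall was chosen over Zhang–Suen after measuring end-of-line erosion
on bar-shaped objects: on a 21×3 px bar Zhang–Suen retains 18 px of
centerline, Guo–Hall 19 px, and less end erosion matters because
mitochondria at this pixel size are short relative to their width.
One-pixel spur branches attached to a junction are pruned (digitization
spurs on thick tubes), then length is the sum over adjacent
skeleton-pixel steps — 1 px for axial, $\sqrt 2$ px for diagonal steps,
each adjacent pair counted once and diagonal steps that short-circuit an
axial path skipped — converted to µm. For branched skeletons the length
is the total over all branches. This chain-code metric carries the
classical digitization bias (a few percent, orientation-dependent); no
corrective weights are applied because the plain 1/$\sqrt 2$ metric is
the conventional definition.

**Aspect ratio.** The ratio of major to minor axis of the
intensity-unweighted second-central-moment ellipse of the object's pixel
set (axis length $4\sqrt{\text{eigenvalue}}$), with the minor axis
floored at 1 px so 1-px-thin lines yield a finite, large ratio.

**Size filter.** Objects with skeleton length in the closed interval
[1, 20] µm are retained; shorter objects are counted as noise specks and
longer ones as fused networks, reported separately rather than silently
dropped, since network-dominant cells are biologically meaningful but
are scored by other means. Skeleton length is the filter metric because
the measurement step is skeleton-based; a major-axis alternative is
available by configuration. Border-touching objects are flagged and
included by default.

# JC-1 membrane-potential profiling

JC-1 accumulates in mitochondria in a potential-dependent manner: green
monomer fluorescence dominates at low $\Delta\psi_m$, red J-aggregate
fluorescence at high $\Delta\psi_m$, so the red/green ratio is a
$\Delta\psi_m$ proxy and its spatial structure reveals "mosaic"
potential along tubular networks.

Segmentation takes the **union** of the per-channel Otsu masks
("combined red/green thresholding"): a mitochondrion bright in only one
JC-1 form — fully depolarized or fully polarized — must not vanish from
the analysis, which an intersection would cause; a sum-channel mode is
available by configuration. Connected components are 8-connected.

Per object, the principal axis is the leading eigenvector of the
intensity-weighted covariance of pixel coordinates (weights = red +
green, making the axis robust to mask-dilation halos; unweighted PCA is
available). The axis sign is fixed (row component ≥ 0) for determinism;
objects whose eigenvalue ratio is below 1.2 are flagged near-isotropic.
Both channels are sampled along the axis by bilinear interpolation
(0.25 px steps) and each profile is normalized to its own maximum — the
per-profile reading of "normalized to their respective maxima"; a
per-image normalization mode exists for cross-object comparisons. The
red/green ratio is computed only where normalized green exceeds 0.05 to
avoid division blow-ups. Per object the pipeline also reports the
pixel-wise red–green PCC within the object mask ("pix PCC": negative
values flag spatially segregated potential) and the variance of the
axial ratio (a mosaicism readout). All-zero profiles are flagged, not
divided. Objects are *not* passed through the 1–20 µm morphometry
filter: the two pipelines are independent analyses.

# Synthetic fields and what they do (not) establish

The generator builds images whose ground truth is exact by
construction, enabling closed-loop validation of every stage:

* **Tube fields** (`make_tube_field`): Catmull–Rom centerlines through a
  heading-capped random walk, cut to an exact analytic arc length (the
  recorded truth), rendered as Gaussian cross-sections by max-composite
  splatting. `width_px` (default 2–5 px) is the approximate full tube
  width, i.e. cross-section $\sigma$ = width/2, so that default tubes
  match the Frangi scale range 1–4.
* **Colocalization fields** (`make_coloc_field`): `round(f·n)` of the
  `n` channel-A Gaussian spots are duplicated at identical positions in
  channel B; all remaining spots sit at disjoint positions with minimum
  separation $4\sigma$ (dart throwing; infeasible densities raise an
  error). Per-spot amplitudes jitter by ±30%. Truth records the designed
  fraction and the analytic intensity overlap.
* **JC-1 fields** (`make_jc1_field`): tubes whose red/green amplitudes
  follow a designed axial pattern — `uniform`, `half-half` (logistic
  switch at mid-arc) or `gradient` (linear crossover) — emulating
  uniform, boundary and mosaic potential distributions.

Noise model: a smooth background (level 100, optional lateral gradient)
is added, Poisson shot noise is drawn with mean `clean × poisson_scale`
(default 0.1) and rescaled, Gaussian read noise (sd 50) is added, and
the result is clipped at 0 and quantized to 16-bit. With the default
amplitude of 1000 this corresponds to a peak signal-to-noise ratio of
about 9 (amplitude divided by the total noise sd at peak intensity), a
realistic live-cell confocal regime. Defaults: 512×512 fields at
0.1 µm/px, a typical high-NA confocal sampling — a generator default
only, not a claim about any particular dataset.

What the synthetic fields do **not** emulate: a physically accurate
PSF (the Gaussian cross-section stands in for it), 3-D structure,
out-of-focus haze, camera-specific noise correlations, or crowded
touching organelles (tubes are placed with a minimum separation).
Passing these benchmarks therefore demonstrates correctness of the
algorithms under controlled conditions, not performance on arbitrary
real micrographs.

# Validation design and observed behavior

The test suite validates each statistic against an independent
brute-force implementation (exact to $10^{-10}$), the Otsu threshold
against exhaustive between-class-variance search (exact), labeling
against a flood-fill oracle, and each pipeline against generator truth.
Problem sizes were chosen so the full suite runs in a couple of minutes:
100 random 32×32 fields for the statistic oracles, 20 seeds × 200 spots
per designed overlap fraction, 10 tube fields × 8 tubes for length
recovery, 20 images per condition for the two-condition discrimination,
and 100 seeds for the mosaic-sign property.

Two behaviors are worth knowing about:

* **Thresholded Manders under noise is biased low.** With independent
  per-channel noise and amplitude jitter, a few percent of a channel's
  masked intensity falls just outside the other channel's mask even for
  perfectly colocalized spots; mean recovered $M_1$ runs at about
  $0.90 f$ under the default noise. Recovery of the designed fraction is
  asserted within ±0.10, and the noiseless pipeline recovers the f = 0.7
  design within ±0.05.
* **Skeleton-length recovery is measured through the tubeness route.**
  Frangi + global Otsu masks terminate near the true centerline ends
  (the vesselness response decays where a ridge ends), so thinning
  erosion and cap extension roughly cancel; ~97% of tubes measure within
  10% of their true length at the default SNR. Raw intensity-Otsu masks
  inflate under noise (wider caps, wiggly boundaries) and reach only
  ~74% — one reason the tubeness step exists.

# Known limitations

* Per-image auto-scaling of the Frangi $\gamma$ makes the filter
  gain-invariant, which is what lets one global threshold compare
  conditions fairly — but it also means an image containing *no* real
  structure has its noise ridges amplified to the response range of
  structured images. Structure-free noisy fields can therefore yield
  spurious objects; in practice every field contains cells, and flat
  (signal-free) images are handled exactly (zero response, no objects).
* The scan-line objective is a package design choice; line-PCC values
  are not numerically comparable across tools.
* No watershed splitting: touching mitochondria merge into one object.
  No 3-D support, no time-lapse registration, no Costes randomization
  p-values, and no absolute $\Delta\psi_m$ calibration in mV.
* The JC-1 axial Spearman statistic is reported as an absolute value:
  the PCA axis sign convention is arbitrary relative to a tube's
  designed gradient direction.
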