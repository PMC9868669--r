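---
title: "Methods: quantifying scaffold-mediated Kv channel clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying scaffold-mediated Kv channel clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(kvclust)
```

# The measurement model

The pipeline quantifies punctate clustering of a membrane channel from
two-channel images of the basal membrane plane: a red channel carrying the
Kv-channel-associated signal, a green channel carrying the scaffold
(PSD-95) signal, and a boolean cell mask. Pixels are square with pitch
0.15 μm (Nyquist sampling for a ~150 nm lateral resolution); all physical
areas are `pixel count × pixelSizeUm^2`.

Five quantities are computed per cell:

* **IFS_T** — total in-mask red signal, corrected by the *camera*
  background (median intensity outside the cell mask). The diffuse,
  non-clustered channel pool is part of IFS_T: it is channel signal, not
  background.
* **surface expression** — IFS_T divided by the mask area (IFS/μm²).
* **clusters per μm²** — retained clustering sites divided by mask area.
* **fraction of channels in clusters** — Σ IFSc / IFS_T, clipped to [0, 1].
* per-site **area** (μm²) and **density** IFSc/area (IFS/μm²), pooled over
  the thousands of sites of a condition rather than averaged per cell,
  because site-level quantities carry site-level sample sizes.

IFSc itself is corrected by the *in-cell* background (median over in-mask
pixels outside all retained sites), which includes the diffuse pool; a
site's density therefore measures the clustered excess over the local
membrane level. Using one background for IFSc and another for IFS_T is a
deliberate asymmetry: a single in-cell estimate would subtract the diffuse
pool from IFS_T as well and force the clustered fraction toward 1
regardless of the data, while a single camera estimate would add the
diffuse pedestal under every site to its "clustered" signal. With the two
estimates, the fraction reaches 1 exactly in the degenerate case where all
signal is clustered (the two backgrounds then coincide) and equals the
clustered share of channel signal otherwise. `cellMetrics(rawIfsT = TRUE)`
disables the IFS_T correction for comparisons.

# Spot detection

`detectSpots()` scans a `boxSize × boxSize` window (default 5 px). A pixel
is a spot when it is the maximum of its window and exceeds the mean of the
window's four corner pixels by more than `noiseTolerance`. The default
tolerance is per image: 3 × 1.4826 × MAD of in-mask intensities, a robust
3-sigma rule that ignores the bright minority of cluster pixels; it is a
plain number and fully overridable. Numerical conventions, chosen for
determinism where a plateau or border leaves the rule ambiguous:

* windows truncated by the image border are skipped (their corners are
  undefined);
* among equal-valued maxima the row-major-first pixel is reported;
* no two accepted spots may lie within one box window (Chebyshev distance
  < `boxSize`); the higher peak wins, ties again row-major.

Corner-mean subtraction cancels any global intensity offset, so the spot
set is offset invariant — a property the tests exercise, together with
exact equivalence to an exhaustive window-scan oracle.

# Segmentation

In-mask pixels strictly above a threshold form a binary map; its
8-connected components containing at least one spot become clustering
sites. The default threshold is Otsu's method computed over in-mask pixels
only (per cell, overridable): the in-mask histogram is strongly bimodal
(diffuse pedestal vs. cluster disks), which is Otsu's home ground. Further
conventions:

* a component holding several spots is **one** site — the analysis counts
  clustering sites, not peaks; no watershed splitting by default;
* spotless components are discarded as threshold noise;
* per-pixel background-corrected values are summed and the site total is
  floored at 0 (per site, not per pixel), so unbiased noise cancels within
  a site instead of rectifying;
* a site touching the mask border keeps its in-mask pixels only.

Co-localization: a site is scaffold-positive when its mean green intensity
exceeds `factor` (default 2) times the median in-mask green intensity.
Density statistics use all sites, with the co-localization flag reported
alongside, since the acquisition design makes sites scaffold-dependent in
the first place.

# The composition model and the linear law

With preference-free assembly of four subunits at A-fraction `fA`, the
A-count per tetramer is Binomial(4, fA) (`compositionDistribution()`,
verified in tests against exhaustive enumeration of the 2⁴ labelled
tetramers; positional isomers are collapsed into counts). If each A subunit
contributes an equal increment to site density — the additive closure used
by the simulator, `d(k) = dB + (dA − dB)·k/4` — the binomial expectation
collapses to the linear law `d(fA) = dB + (dA − dB)·fA`. The additive
closure is this package's modelling choice for generating data; the
empirical claim it supports is only the linear dependence itself, which
`fitDensityVsFraction()` quantifies (OLS; `R² = 1 − SS_res/SS_tot`, defined
as 0 with a degeneracy flag when the responses are constant).

# The inference cascade

`statsCascade()` reproduces the study-level decision procedure per metric:

1. per-group normality by Kolmogorov–Smirnov with Lilliefors correction —
   parameters estimated from the sample, null distribution simulated
   (default 10,000 Monte-Carlo samples under a fixed internal seed, cached
   per sample size, p = (1 + #[D* ≥ D])/(B + 1)); a zero-variance group is
   flagged and its p set to 0;
2. homoscedasticity by Levene's test, center = mean;
3. selection: both pass → ANOVA; only normality violated → Welch; only
   homoscedasticity violated → Kruskal–Wallis; both violated → transform
   (log for area-type metrics, sqrt for density-type) and re-assess once,
   then select again; if both assumptions still fail, fall back to
   Kruskal–Wallis with a warning. Assumption checks run at α = 0.05,
   hypothesis rejection at α = 0.01, Tukey HSD only after rejection.

The normality→Welch / heteroscedasticity→Kruskal–Wallis mapping is kept
exactly as the study design states it, although the conventional pairing is
the reverse; `mapping = "conventional"` switches to the textbook mapping.
Fidelity to the documented procedure was preferred over correcting it,
because the package's job includes reproducing the original decisions.
Non-positive values under log/sqrt are shifted by `−min + ε` with a
warning. Monotone transformations cannot change Kruskal–Wallis (it is
rank-based), and for two groups ANOVA-F equals the squared pooled-t and
Tukey reduces to the pooled t test — identities the tests assert.

# What the simulator emulates — and what it does not

`sceneParams()` defaults describe one condition of the emulated study:
256×256 px at 0.15 μm/px; an elliptical cell of ~600 μm² (semi-axes
100×85 px, jittered ±5% per seed); 0.25 clustering sites/μm² (so 23 cells
give ~3,000–5,000 sites per condition); site radii lognormal with median
0.33 μm, sdlog 0.12; per-site densities Gamma with mean `meanDensity`
(condition endpoints 16.51 and 20.33 ×10⁴ IFS/μm² for the pure-B and
pure-A tetramers) and CV 0.30; a diffuse level of 1,800 intensity
units/px, putting the clustered fraction near 0.13–0.20; camera background
400; Gaussian read noise sd 200 (clamped at 0); scaffold co-localization
probability 0.9. Sites are uniform-intensity disks with per-pixel amplitude
`density × pixelSize²`, placed by rejection sampling with minimum centre
distance the sum of the two radii and the whole disk inside the mask, so
every metric has an exact analytic ground truth (`trueMetrics()`).

Deliberate departures from realism, made for testability:

* **Uniform disks, no PSF.** Real puncta are diffraction-blurred blobs;
  disks make area and integrated signal exact. No optical transfer
  function, axial structure, or detector model is simulated.
* **Site areas are super-resolution-scale, not the study scale.** The
  emulated study reports mean site areas of ~1.5×10⁻² μm² — about 0.7
  pixel at 150 nm sampling. Sub-pixel disks cannot be segmented with
  bounded area error by any threshold method, so the default radii
  (~2.2 px) are the smallest at which threshold segmentation recovers area
  and density within 10%. Density endpoints, site counts, cell counts and
  clustered fractions match the study scales; site area (and hence surface
  expression, which is coupled to the others through the fraction
  identity) does not. Recovery claims therefore concern the method, not
  the instrument. The published per-metric scales are in any case not
  jointly satisfiable by any generative model, since fraction × surface
  expression and sites × area × density disagree by an order of magnitude.
* **Noise statistics are assumed, not measured.** The acquisition's noise
  and dynamic range are not documented; additive truncated-Gaussian read
  noise (shot noise off by default) at sd 200 makes the faintest plausible
  sites ~7 sigma above the diffuse level. Passing recovery tests shows the
  pipeline is accurate under these conditions, not under arbitrary SNR.

Reproducibility: `makeScene()` draws everything from `params@seed`;
`renderScene()` adds noise under `seed + 7919`, so geometry and rendering
are separately deterministic, and condition/cell seeds derive from one
master seed. Degenerate inputs fail loudly: an empty mask errors, an
unplaceable site density errors after 100× the target count in attempts
(reporting the attained count), a threshold above the image maximum warns
and returns an empty site set, and a zero-IFS_T cell with sites is flagged
invalid and excluded from aggregation.

# Problem sizes used by the tests

The test-suite simulations are sized to exercise every claim on a single
CPU in about a minute: most fixtures use ~76 μm² cells on 96×96 px images
(~19 sites each); the end-to-end recovery check runs the full study
geometry, 5 conditions × 23 cells at 256×256 px (~15,000 sites), and
requires every condition-mean density within 10% of ground truth (observed
errors are below 2%); the cascade's type-I error is estimated from 2,000
null ANOVA simulations; null tables for the normality test use reduced
Monte-Carlo sizes (B = 300–400), which only need enough resolution to
classify at the 0.05 level.

# Known limitations

* Sites separated by less than a box width can merge (one component, one
  or two suppressed spots), slightly deflating counts (~5–10% at default
  densities) and inflating areas; density means are nearly unbiased
  because a merged site's density is the average of two draws from the
  same distribution.
* Detection probability rises with site density, so very low-density sites
  are under-sampled; at default parameters this biases condition means by
  under 2%.
* Clusters are analyzed as independent observations within a condition
  (sites nested in cells are pooled); no mixed-effects modelling.
* The homogeneous-subset grouping sometimes reported for clustered
  fractions is not reproduced as such; the Tukey table carries the
  pairwise information from which such groupings derive.
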