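# kvclust

Quantitative clustering metrics for scaffold-mediated voltage-gated potassium
(Kv) channel clusters in two-channel fluorescence micrographs.

## The problem

Shaker-type Kv channels are clustered at specific membrane sites by the
scaffold protein PSD-95, which binds a PDZ motif at the tip of the channel's
intrinsically disordered C-terminal "chain". Alternative splicing produces a
short-chain, high-affinity subunit (*A*) and a long-chain, low-affinity
subunit (*B*); because the channel is a tetramer, co-expressing both at a
molar fraction *f*<sub>A</sub> = [A]/([A]+[B]) yields hetero-tetramers whose
A-subunit count *k* is binomial, *P(k) = C(4,k) f*<sub>A</sub>*<sup>k</sup>
(1−f*<sub>A</sub>*)<sup>4−k</sup>*. The quantity of interest is how cluster
channel density — background-corrected integrated fluorescence per unit
cluster area, IFSc/μm² — changes along the *f*<sub>A</sub> axis.

`kvclust` implements the full analysis chain for this question, aimed at
cell-biology groups quantifying punctate membrane-protein clustering from
confocal images:

1. **Synthetic scenes** (`makeScene()`, `renderScene()`,
   `generateCondition()`) — ground-truth-annotated two-channel cells
   (Poisson cluster counts, lognormal radii, Gamma per-cluster densities,
   diffuse pool, camera background, read noise) so the whole pipeline is
   testable without microscope data.
2. **Spot detection** (`detectSpots()`) — local maxima found by scanning a
   box across the image; a peak is accepted when it exceeds the mean of the
   box's four corner pixels by more than a noise tolerance.
3. **Segmentation** (`segmentClusters()`) — in-mask thresholding (Otsu by
   default), 8-connected components containing at least one spot become
   clustering sites; per site: area, background-corrected integrated signal
   IFSc, density IFSc/area, and scaffold co-localization.
4. **Per-cell metrics** (`cellMetrics()`, `aggregateCondition()`) — total
   signal IFS_T, surface expression IFS_T/μm², clusters/μm², fraction of
   channels in clusters ΣIFSc/IFS_T, aggregated per condition with
   standard errors.
5. **Composition model and regression** (`compositionDistribution()`,
   `expectedMeanDensity()`, `fitDensityVsFraction()`) — the binomial
   tetramer model and the ordinary least-squares fit of condition-mean
   density on *f*<sub>A</sub>.
6. **Inference cascade** (`statsCascade()`) — Lilliefors-corrected
   Kolmogorov–Smirnov normality and Levene homoscedasticity checks, test
   selection (ANOVA / Welch / Kruskal–Wallis, with one log- or
   sqrt-transformation round), rejection at α = 0.01, Tukey HSD post-hoc.
7. **Orchestration** (`runPipeline()`) — reproducible end-to-end runs with
   TIFF/CSV/JSON artifacts, each tagged with a configuration hash.

## Worked example

```r
library(kvclust)

scene <- makeScene(sceneParams(seed = 1L))   # one synthetic cell
scene
#> SyntheticScene: 147 clusters on a 579.51 um^2 cell
#>   true fraction in clusters: 0.1713 | true mean density: 184808 IFS/um^2

img <- renderScene(scene)
res <- analyzeCellImage(img, cellId = "cell01")
res$clusters
#> ClusterSet: 133 clustering sites; background = 2203.37 ; threshold = 4344.25
#>   mean area: 0.3658 um^2 | mean density: 185821 IFS/um^2 | coloc: 0.902
res$metrics
#> CellMetrics [ cell01 ]
#>   area: 579.51 um^2 | IFS_T: 55947600 | surface expr: 96543 /um^2
#>   clusters/um^2: 0.2295 | fraction in clusters: 0.164 ( 133 sites )
```

The detector/segmenter recovers the generative truth closely: 133 of 147
sites found (close pairs merge; a handful of faint sites fall below the
noise tolerance), the pooled mean cluster density is 185,821 against a true
184,808 IFS/μm² (+0.5%), and the measured clustered fraction 0.164 tracks
the true 0.171.

Fitting the five published condition-mean cluster densities (in units of
10⁴ IFS/μm² at *f*<sub>A</sub> = 0, 0.25, 0.5, 0.75, 1):

```r
tab1 <- data.frame(f_A = c(0, 0.25, 0.5, 0.75, 1),
                   density = c(16.51, 17.89, 18.81, 20.62, 20.33) * 1e4)
fitDensityVsFraction(tab1)
#> RegressionFit: y = 167580 + 41480 * f_A ; R^2 = 0.9175 ( 5 points )
```

i.e. R² = 0.92: cluster channel density rises linearly with the transfected
high-affinity subunit fraction, as the additive binomial-subunit model
predicts (`expectedMeanDensity()` shows the two forms coincide).

```r
compositionDistribution(0.5)
#> Tetramer composition at f_A = 0.5
#>     k0     k1     k2     k3     k4
#> 0.0625 0.2500 0.3750 0.2500 0.0625
#> mean A subunits per tetramer: 2
```

A full five-condition simulated study (`runPipeline(pipelineConfig())`)
writes spots, clusters, per-cell metrics and a condition summary CSV plus
stats-report and regression JSONs; `inst/scripts/kvclust.R` wraps it for
shell use.

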