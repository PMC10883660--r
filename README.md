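# olivemotion

Quantification of visual-motion responses in inferior-olive (IO) neurons
recorded by calcium imaging in larval zebrafish, and of how well the
resulting functional maps match the nucleus's anatomical organization.

The package is for systems-neuroscience analysts working with
direction-tuned calcium responses: it turns per-ROI fluorescence traces
and volumetric response stacks into per-stimulus dF/F0 responses, applies
a baseline + 2 SD responding/active criterion, computes a vector-sum
direction-selectivity index with a 1,000-shuffle permutation test,
quantifies eye dominance with a monocular index and per-eye preferred
directions, categorizes voxels of light-sheet stacks by motion preference,
and scores functional-vs-anatomical overlap with a kernel-density matching
score and a bootstrap-calibrated matching index. A seeded synthetic-data
generator (von Mises tuning, exponential indicator kinetics, configured
topography) supplies ground-truth-labeled populations so the whole chain
is testable without the original imaging data.

## The statistics at the core

For mean responses `r_i >= 0` (negatives rectified) at the eight grating
directions `theta_i` (0° forward, 90° rightward):

    DSI = | sum_i r_i exp(i theta_i) | / sum_i r_i
    PD  = arg( sum_i r_i exp(i theta_i) )

so a single-stimulus responder has DSI 1 and a uniform responder DSI 0.
Selectivity is judged against a null built by shuffling direction labels
across individual presentations 1,000 times (selective iff DSI > the 95th
null percentile). Eye dominance is `(contra − ipsi)/(contra + ipsi)` of
direction-averaged responses, in [−1, 1]. Overlap between a functional and
an anatomical class pair uses 2D kernel densities (Gaussian SD 10 px =
7.8 µm): the matching score `MS(p, q) = ∫ min(p, q)` in [0, 1], the
matching index `MI = mean(MS, matched pairing) − mean(MS, opposite
pairing)` in [−1, 1], tested one-tailed against a 10,000-resample
bootstrap null at the Bonferroni-corrected 99.17th percentile
(= 100 − 5/6, six comparisons), requiring significance in both the soma
and axon-terminal regions.

## Worked example

```r
library(olivemotion)

cfg <- runConfig(
  population = populationSpec(
    n_per_class = c(forward = 20, backward = 20, cw_rotation = 8,
                    ccw_rotation = 8, nonselective = 14),
    seed = 1),
  n_shuffles = 1000, n_boot = 2000, grid_spacing = 2, seed = 42)
rep <- runPipeline(cfg)
summarizeRun(rep)
#>                          quantity               value
#> 1                  active neurons        70/70 (100%)
#> 2 direction-selective (of active)       56/70 (80.0%)
#> 3                        class DS                  40
#> 4                    class DS+CCW                   8
#> 5                     class DS+CW                   8
#> 6                  MI soma region 0.576 (thr 0.070) *
#> 7              MI neuropil region 0.637 (thr 0.047) *
#> 8         matched in both regions                 yes
```

All 70 synthetic neurons pass the responding criterion (the generator's
default SNR is high); 56 of them — exactly the tuned classes, none of the
14 direction-uniform ones — are flagged direction selective, and the
rotation-responsive classes land in DS+CW / DS+CCW. The matching index
between the forward/backward functional split and the unipolar/multipolar
anatomical clusters is far above its bootstrap threshold in both regions,
recovering the configured topography:

```r
rep$overlap$soma
#> MatchResult
#>   matching scores:
#>            forward backward
#> unipolar    0.8774   0.2988
#> multipolar  0.1953   0.7685
#>   MI = 0.5759; null 99.17th percentile = 0.0703 (2000 resamples) -> significant
```

Individual stages are exported too — `generateProtocol()`,
`responseTable()`, `computeDsi()`, `shuffleTest()`, `monocularIndex()`,
`categorizeVoxels()`, `matchingScore()`, `overlapTest()` — see the
vignette `vignettes/olivemotion-methods.Rmd` for the model, the parameter
conventions and the design decisions.

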