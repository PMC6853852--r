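# octlayers

Fully automatic annotation of retinal layers in optical coherence
tomography (OCT) B-scans. Given a single grayscale B-scan (rows = axial
depth, columns = lateral position), `octlayers` extracts the 8 interfaces
delimiting the 7 retinal layers — ILM, NFL-GCL, IPL-INL, INL-OPL, OPL-ONL,
IS-OS, OS-RPE, RPE-Choroid — and derives layer masks and quality metrics.
It is aimed at ophthalmic image-analysis researchers who need repeatable
layer delineations (e.g. retinal nerve fibre layer thickness for glaucoma
work) without manual tracing.

## Method

1. **Fuzzy histogram hyperbolization (FHH).** Grey levels are mapped to
   memberships `mu = (g - g_min) / (g_max - g_min)` and transformed by
   `g' = (L-1)/(e^{-1}-1) * (exp(-mu^beta) - 1)`. The fuzzifier `beta` is
   set per image from the linear index of fuzziness
   `gamma = 2/(MN) * sum(min(mu, 1-mu))` as `beta = clamp(4*gamma + C,
   T_min, T_max)`, which suppresses speckle and intensity inhomogeneity
   while preserving edges.
2. **Gradient graphs.** The normalized vertical gradient (dark→bright) and
   its inverse (bright→dark) define two 8-connected pixel graphs with edge
   weights `w_ab = 2 - g_a - g_b + w_min`, re-assigned by a fuzzy power
   transform `w'' = ((w - w_mn)/(w_mx - w_mn))^beta_w` so edges along layer
   transitions become cheap. A virtual minimum-weight column on each side
   lets paths enter and exit at any row.
3. **Sequential graph cut.** Dijkstra shortest paths extract the
   boundaries in the order ILM, IS-OS, RPE-Choroid, NFL-GCL, OS-RPE,
   INL-OPL, IPL-INL, OPL-ONL, each search limited to the band between
   previously found boundaries, exploiting the reflectivity priors of
   retinal anatomy.

Evaluation metrics (boundary MAD and RMSE in pixels, layer Dice, and
RNFLT accuracy / sensitivity / error rate) and a synthetic B-scan
generator with known ground truth, correlated gamma speckle and vessel
shadows are included, so the whole pipeline is testable without clinical
data.

## Worked example

```r
library(octlayers)

sim <- simulate_bscan(phantom_spec(seed = 3))   # 256x512, speckle + shadows
seg <- oct_pipeline(sim$image, verbose = TRUE)
#> FHH: gamma = 0.3972, beta = 2.0886
#> ...
#> ordering invariant: ok
ev <- evaluate_segmentation(seg, sim$boundaries, height = 256)
print(ev)
#> <oct_eval>
#>     boundary         mad       rmse
#>          ILM 0.003906250 0.06250000
#>      NFL-GCL 0.019531250 0.13975425
#>      IPL-INL 0.052734375 0.22963966
#>      INL-OPL 0.045730886 0.23385359
#>      OPL-ONL 0.013671875 0.11692679
#>        IS-OS 0.009765625 0.09882118
#>       OS-RPE 0.874862665 1.87864230
#>  RPE-Choroid 0.001953125 0.04419417
#> layer Dice:
#>     NFL GCL+IPL     INL     OPL  ONL+IS      OS     RPE
#>  0.9994  0.9988  0.9975  0.9983  0.9997  0.9687  0.9674
#> RNFLT:
#>    accuracy sensitivity  error_rate        dice
#>      0.9999      0.9988      0.0000      0.9994
```

The `mad` column is the symmetric mean distance (pixels) between each
segmented boundary and the ground truth — well under a pixel everywhere,
with the faint OS-RPE interface the hardest. `layer Dice` is the overlap
of each derived layer mask with truth, and the RNFLT block scores the
nerve-fibre band (ILM to NFL-GCL) pixel-wise. On the noise-free phantom
the recovery is exact (all MAD and RMSE 0, all Dice 1).

Boundary tables export with `write_boundaries()` (CSV, one row per image
column, 0-based rows in original pre-crop coordinates) and
`write_overlay()` draws all 8 boundaries on the scan for visual QC.
A thin command-line front end with `simulate`, `enhance`, `segment` and
`eval` subcommands is installed at `inst/cli/octlayers.R`.

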