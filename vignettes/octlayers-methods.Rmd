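---
title: "Methods: fuzzy enhancement and graph-cut retinal layer annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy enhancement and graph-cut retinal layer annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlayers)
```

## The problem

A macular OCT B-scan is a cross-sectional image whose rows encode axial
depth and whose columns are adjacent A-scans. Seven retinal layers — NFL,
GCL+IPL, INL, OPL, ONL+IS, OS and RPE — are delimited by eight interfaces
running laterally across the whole image, from the inner limiting membrane
(ILM) down to the RPE–choroid interface. Delineating them manually is slow
and rater-dependent; automating it is complicated by speckle (multiplicative,
non-Gaussian, spatially correlated noise inherent to coherent imaging),
intensity inhomogeneity, and the shadows that retinal vessels cast down the
scan. `octlayers` annotates all eight interfaces fully automatically in
three stages: contrast enhancement, graph construction, and sequential
shortest-path extraction.

## Fuzzy histogram hyperbolization

Grey levels are first mapped to a fuzzy membership plane with the min–max
membership

$$\mu(g) = \frac{g - g_{\min}}{g_{\max} - g_{\min}},$$

and the image's *linear index of fuzziness*

$$\gamma(I) = \frac{2}{MN}\sum_{m,n} \min\!\big(\mu_{mn},\, 1 - \mu_{mn}\big)$$

measures how far the memberships are from crisp $\{0,1\}$ ($\gamma = 0$ for
a binary image, $\gamma = 1$ when every $\mu = 0.5$). The enhanced grey
level is the hyperbolic transform

$$g' = \frac{L-1}{e^{-1}-1}\left(e^{-\mu^{\beta}} - 1\right),$$

monotone in $\mu$, spanning exactly $[0, L-1]$. The fuzzifier $\beta$
interpolates between histogram-equalization-like behavior ($\beta \to 0$)
and segmentation-like quantization ($\beta \gtrsim 5$). Because denoising
results are sensitive to such parameters, $\beta$ is chosen per image from
the only image-level fuzzy statistic available, $\beta_0 = k\,\gamma(I)$
with $k = 4$ by default, then stabilized by an additive constant $C$ and
clamped to an admissible window:

$$\beta = \mathrm{clamp}(\beta_0 + C,\; T_{\min},\; T_{\max}).$$

Defaults $T_{\min} = 0.5$, $T_{\max} = 5$, $C = 0.5$ put typical retinal
scans near $\beta \approx 2$, inside the window where the transform
sharpens layer contrast without quantizing. The stabilization is applied
once, not iterated. The mapping from image statistics to $\beta_0$ is a
genuinely open design point — only the clamping rule is prescribed by the
method — and $k\,\gamma(I)$ was chosen because it is adaptive per image,
uses no user input, and reduces to the stated window behavior at the
extremes. `fhh_enhance()` reports the $\gamma$ and $\beta$ it used;
`beta_override` fixes $\beta$ verbatim for experiments. Enhanced
intensities are kept as doubles; rounding to the grey grid happens only on
image export, so downstream gradients keep full precision.

## Gradient graphs and fuzzified weights

The vertical first difference $D(r,c) = I(r,c) - I(r-1,c)$ is positive
where intensity increases with depth. Row 1, which has no predecessor,
replicates row 2's value rather than padding with zero — a zero pad would
fabricate a mid-scale "no change" response at the image top. $D$ is min–max
normalized to $[0,1]$ over the whole image (global scope, so transition
strengths remain comparable across the scan); this is the dark→bright map,
and its pointwise inverse $1 - \cdot$ is the bright→dark map. Each map
yields one undirected pixel graph (8-connected by default; sloped
boundaries need diagonal steps; 4-connectivity is available) with edge
weights

$$w_{ab} = 2 - g_a - g_b + w_{\min},$$

so edges along a strong transition of the map's polarity cost about
$w_{\min}$ and edges in homogeneous tissue about $2 + w_{\min}$.
$w_{\min} = 10^{-5}$ keeps all weights strictly positive (required by
Dijkstra) while staying far below any informative weight.

To re-emphasize both continuity and discontinuity the weights are then
fuzzified: min–max normalized over all edges of the graph and raised to a
constant exponent $\beta_w$ (default 2, exposed in the configuration; a
constant is used rather than a per-graph fuzziness computation to keep the
cost of processing millions of edges down). The power map is monotone on
$[0,1]$, so edge ranking is preserved, but low-cost edges are pushed much
lower. Since the normalization maps the globally cheapest edge to exactly
0 — which would create free paths — $w_{\min}$ is added back as a floor.

Because every boundary spans the full width, one virtual column is appended
on each lateral side whose edges all cost $w_{\min}$; a path can enter or
leave the image at any row essentially for free (traversing a whole virtual
column costs $(H-1)\,w_{\min}$). The phrase "two columns added to either
side" in the antecedent literature is read as two columns in total; one per
side suffices for free vertical movement. The source is the top of the left
virtual column, the sink the top of the right one, and the minimum-weight
path between them is found with Dijkstra's algorithm (via `igraph`). Ties
between equal-cost paths are resolved deterministically by the fixed
edge-insertion order of the graph construction; identical input and
configuration always reproduce identical boundaries, which is the property
the tests assert.

## Sequential segmentation with anatomical priors

Graph cuts find one boundary at a time, so the eight interfaces are
extracted sequentially, each search limited by boundaries already found
(`limit_region()` removes nodes outside the band; a margin of 1 px is
excluded next to each delimiting boundary so it cannot be re-found — the
exact margin is not prescribed anywhere, and 1 px is the smallest value
that prevents re-finding). The order and polarities encode the standard
reflectivity priors of macular SD-OCT — NFL, the IS-OS complex and RPE are
the hyper-reflective bands:

1. **ILM** — strongest dark→bright transition, full image (vitreous above
   it is dark and vessel-free);
2. **IS-OS** — dark→bright below the first path; the two candidates are
   then labeled by mean vertical position (ILM lies above IS-OS);
3. **RPE-Choroid** — strongest bright→dark transition, full image by
   default (`rpe_below_isos` restricts the search below IS-OS for noisy
   scans);
4. **NFL-GCL** — bright→dark between ILM and IS-OS;
5. **OS-RPE** — dark→bright between IS-OS and RPE-Choroid;
6. **INL-OPL** — dark→bright between NFL-GCL and IS-OS (the only
   dark→bright interface in that band);
7. **IPL-INL** — bright→dark between NFL-GCL and INL-OPL;
8. **OPL-ONL** — bright→dark between INL-OPL and IS-OS.

When the 8-connected path visits several rows of one column, the last
visited row is recorded, keeping boundaries single-valued. A stage whose
region is empty or disconnected aborts with the stage name. After all eight
stages the top→bottom weak ordering of the boundaries is checked; a
violation is flagged in the result, never silently repaired, because a
crossing indicates the priors failed on that scan and the output should not
be trusted.

Scans are pre-processed by cropping 15% of the height from the top
(`crop_fraction`), removing the low-signal vitreous band; the crop offset
is carried through so exported boundaries are in original image
coordinates (0-based in CSV exports, 1-based inside R).

## Evaluation metrics

Boundary agreement is measured by MAD — the symmetric mean nearest-point
distance between the two boundary curves read as 2D pixel point sets,
$0.5(\frac{1}{n}\sum_i d(pt_i, SEG) + \frac{1}{m}\sum_i d(ps_i, GT))$ with
Euclidean $d$ — and by the per-column RMSE of row differences. Both are
reported in raw pixels. Region agreement uses the Dice coefficient
$2|GT \cap SEG| / (|GT| + |SEG|)$ and, for the retinal nerve fibre layer
band (ILM to NFL-GCL, the key glaucoma biomarker), pixel-wise accuracy,
sensitivity (TPR) and error rate (FPR). Layer masks use the half-open
convention — layer $k$ occupies rows $[b_k, b_{k+1})$ per column — so the
seven masks exactly partition the band between ILM and RPE-Choroid; any
consistent convention gives identical metric comparisons as long as both
segmentation and ground truth use it. Degenerate inputs (empty point sets,
two empty masks, a zero denominator in a confusion ratio) raise errors
naming the metric rather than returning silent zeros.

## The synthetic phantom

No public ground-truthed dataset accompanies the method, so the package
ships a generator whose phantoms make every pipeline stage testable with
known truth. A phantom is a piecewise-constant axial reflectivity profile:
eight smooth interface curves (low-order polynomial tilt and bow, an
optional foveal dip fading from ILM to IS-OS), each layer filled with its
mean reflectivity, then degraded by the two noise sources the method is
designed around:

* **speckle** — each pixel is multiplied by a unit-mean gamma factor
  (shape = `speckle_looks`, default 4, i.e. raw field variance 0.25)
  whose field is box-smoothed (3×3) first, making the noise multiplicative,
  non-Gaussian and neighborhood-correlated while preserving expected
  intensities;
* **vessel shadows** — column bands (two by default) attenuated below the
  ILM with a smooth lateral Gaussian falloff, leaving ground-truth rows
  untouched.

Default geometry is 256×512 with interfaces at rows 60–215 and layer
thicknesses of 15–37 px, proportionate to the 512-deep clinical scans the
method targets at roughly half scale. The default reflectivities
(background 8, NFL 160, GCL+IPL 75, INL 40, OPL 85, ONL+IS 30, OS 145,
RPE 175, choroid 25 on an 8-bit scale) are constrained by the priors the
sequential stages assume, and the constraint must hold *after* enhancement
and under speckle, which stretches the observed grey range towards
$[0, 255]$ and therefore compresses memberships. Writing
$f(\mu) = 1 - e^{-\mu^\beta}$ for the (rescaled) transform at a typical
$\beta \approx 2.2$: the vitreous→NFL step is the largest dark→bright
contrast, ONL→IS-OS the clear second (about twice OS→RPE — an early
reflectivity draft with a brighter OS made these two nearly equal, which
breaks stage 2 exactly as the priors predict), RPE→choroid the largest
bright→dark, and NFL→GCL the largest bright→dark strictly between ILM and
IS-OS, ahead of OPL→ONL for every admissible $\beta \gtrsim 0.7$. Phantom
specs that violate ordering or separation invariants are rejected at
construction.

What the phantom does **not** emulate: pathology (drusen, edema, layer
dropout), the fovea's true layer convergence (the optional dip thins but
never merges layers), axial point-spread blur, depth-dependent signal
roll-off, saturation artifacts, and real speckle's full statistics. Passing
the phantom suite therefore demonstrates the pipeline's correctness and its
robustness to the modeled noise, not clinical-grade accuracy on diseased
eyes.

## Numerical choices and limitations

* Gradient normalization and weight normalization are global per image /
  per graph; both are monotone, so they never reorder transition strengths.
* The weight normalization's min/max are taken over image edges only;
  virtual-column edges keep weight exactly $w_{\min}$.
* A constant image is degenerate everywhere: membership is undefined
  (error), the gradient map falls back to 0.5 with a warning, and
  all-equal edge weights make fuzzification fail fast.
* Boundary rows are integers internally (path nodes); profile curves are
  rounded at generation, so exact noise-free recovery is well-defined.
* Test and acceptance problem sizes — 6×6 grids for oracle equivalence
  against an independent Bellman-Ford implementation, 256×512 phantoms,
  20 speckled seeds — were chosen as the smallest sizes at which every
  stage (including both virtual columns, diagonal steps and all eight
  region limitations) is exercised with comfortable statistical margin.
* Known limitations: the method assumes the reflectivity priors above, so
  scans where pathology inverts a contrast ordering can mislabel
  boundaries (the ordering flag catches crossings, not plausible-looking
  mistakes); 16-bit scans are processed at native depth but the phantom
  generator is 8-bit; and RMSE here is in raw pixels, which can differ in
  scale from published tables whose normalization is unstated.
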