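---
title: "Scoring biofilm growth from stained-coupon photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring biofilm growth from stained-coupon photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgiscore)
```

## The measurement problem

Early biofilm growth on a submerged surface changes its appearance only
subtly. After staining with a broad-spectrum biomolecular dye mixture, a
fouled coupon photographs darker wherever the biofilm is thicker, so color
intensity can carry quantitative information. The classical way to extract
it is binary thresholding: pick a cut (by hand, or by Otsu's
variance-minimizing rule), call everything below it biofilm, and report the
percent areal coverage. Binary coverage fails in two characteristic ways on
coupon photographs: on a nearly uniform early-stage image the optimal
binary cut just splits substrate texture or sensor noise in half, and once
the surface is covered the measure saturates even though the film keeps
thickening and darkening.

The Biofilm Growth Intensity (BGI) score addresses both failures by using
*all* the gradations of darkness instead of one cut.

## The BGI algorithm

For a single channel of a photograph (gray, red, green or blue) restricted
to a user-chosen rectangular region of interest:

1. **Multilevel thresholding.** The 256-bin intensity histogram is divided
   into $N + 1$ classes by $N$ thresholds (default $N = 10$, giving 11
   groups) chosen to minimize the count-weighted within-class intensity
   variance — the multilevel generalization of Otsu's rule. `bgiscore`
   computes the exact global optimum by dynamic programming over cumulative
   count and count-times-intensity sums; no stochastic search is involved,
   so results are bit-reproducible. Quantizing the image to its class
   indices and remapping class $g$ to intensity $\mathrm{round}(255 g/N)$
   stretches the contrast for visual inspection.
2. **Ramp filter.** Each class count is multiplied by a linear weight
   running from 0 for the brightest class to 1 for the darkest class. The
   weighted sum is the filtered histogram area $A_2$.
3. **Score.** With $A_1$ the total pixel count,
   $$\mathrm{BGI} = 100 \cdot A_2 / A_1 .$$
   BGI is 100 exactly when every pixel is in the darkest class and 0 when
   every pixel is in the brightest; equivalently it is 100 times the mean
   ramp weight over pixels. Because the filter is linear in the class
   counts it cannot introduce a spurious nonlinear trend, and because the
   score depends only on the histogram it is invariant to any spatial
   rearrangement of pixels.

Unlike areal coverage, BGI responds to the *density and thickness* of
fouling, not only its extent.

```{r example}
img <- generate_coupon_image(coupon_growth_params(0.7, seed = 1),
                             size = c(200, 200))
analyze_image(img, roi(10, 190, 10, 190))
```

### Conventions and edge cases

* **Class membership.** A pixel of intensity $v$ with threshold $t$
  satisfies "$v \le t$ goes to the lower class"; class 0 collects the
  darkest intensities. One convention had to be fixed; this one is applied
  everywhere and exercised by the tests.
* **Tie-breaking.** When several threshold vectors attain the optimum
  (possible for symmetric or spike histograms), the lexicographically
  lowest vector is returned. The dynamic program uses a suffix formulation
  so ties resolve left-to-right deterministically.
* **Ramp spacing.** The weights are $g/N$ for classes $g = 0..N$, the
  unique equal spacing consistent with the score's defining endpoints
  (all-brightest $\to 0$, all-darkest $\to 100$). A `ramp_denominator`
  option provides the alternative reading in which interior weights step
  by $1/(N+1)$ while the last class still carries weight 1; the endpoint
  behavior is identical either way.
* **Degenerate images.** A single-intensity image cannot be thresholded;
  it is scored by the direct mapping $100(255 - v)/255$, which keeps blank
  and saturated coupons on the scale continuously. An image with
  $d \le N$ occupied levels is scored with $d - 1$ thresholds so each
  occupied level forms its own class. `multilevel_otsu()` itself refuses
  such histograms with a degenerate-histogram error, since no valid
  $N$-threshold partition exists.
* **Grayscale conversion.** ITU-R BT.601 luma weights
  (0.299, 0.587, 0.114) by default — the camera-pipeline standard — with
  `weights = "equal"` for the plain channel mean. Channels are thresholded
  independently: each channel's histogram carries different stain
  information, and a shared threshold set would let one channel's contrast
  dictate another's quantization.

## Comparator methods

`otsu_coverage()` (binary Otsu, dark class = biofilm) and
`manual_threshold()` (a closed intensity range $[low, high]$ marked as
foreground) both reduce to percent areal coverage via `areal_coverage()`.
They are included because ranking BGI against them on a common control is
the package's benchmarking workflow.

## The cell-density control

The independent control is destructive: biofilm is sonicated off a coupon
into a known buffer volume and the suspension's optical density at 600 nm
is read. In the 0–1 AU range OD is roughly proportional to cell
concentration at $3.9 \times 10^8$ cells mL$^{-1}$ per AU (a warning is
issued above 1 AU). Areal density follows from the assay geometry:

$$\text{cells cm}^{-2} =
  \frac{3.9\times 10^8 \cdot \mathrm{OD}_{600} \cdot V_\mathrm{mL}}
       {n_\mathrm{sides} \cdot s_\mathrm{cm}^2},$$

with defaults $V = 15$ mL and two colonized faces of a 2.5 cm square
coupon.

## Ranking image metrics against the control

Cell density grows over orders of magnitude while image scores are linear,
so the control is log10-transformed before comparison (zero densities map
to an assay floor one count below the smallest positive observation; the
transform is optional via `log_control = FALSE`). For each metric the
Pearson correlation $r$ and the slope $m$ of a simple linear regression
are combined into a single 0–1 figure of merit, $r \cdot m$. Two details
make this meaningful:

* both series are min-max normalized to $[0,1]$ before the slope fit, so
  "$m$ nearest 1" is comparable across metrics with different units;
* because $r$ and the OLS slope of the same pair always share a sign, the
  raw product is nonnegative even for a metric that tracks the control
  *inversely*; confining the measure to the 0–1 scale therefore floors
  anti-correlated metrics (negative $r$) at 0 directly rather than relying
  on a clamp of the product.

Replicates are treated as independent paired samples (12 pairs for a
4-time-point triplicate design), not averaged per time point; averaging is
available for sensitivity analysis by aggregating the tables before
`rank_from_tables()`.

## The synthetic coupon generator

Real coupon photographs are not required anywhere in the test suite; the
`synthetic` module generates them. It emulates a 2.5 cm square
green-tinted fiberglass coupon after staining:

* a smooth random patch field $f \in [0,1]$ (sum of ~40 Gaussian bumps at
  ~15 % of the coupon side, min-max normalized so clean substrate
  persists);
* stain opacity $\min(1,\,0.45 + 0.55 g/0.4)\cdot f^{\,k/g}$ for growth
  level $g \in (0,1]$ and onset exponent $k = 0.5$: colonies nucleate at
  field maxima, spread outward and deepen with $g$, and early films stay
  subtle and graded rather than saturated. Opacity is strictly
  nondecreasing in $g$ at every pixel, and $g = 0$ leaves the coupon
  perfectly clean;
* multiplicative compositing toward a purple-hued stain tint, so the red
  and blue channels (strongly absorbed) darken toward saturation first;
* broad weave shading on exposed substrate (peak 22 % darkening),
  developing with the first stain exposure ($g^{0.15}$) and progressively
  hidden where biofilm covers it. This shading is what defeats a binary
  cut on realistic images: shaded clean substrate and genuinely fouled
  area overlap in intensity;
* additive Gaussian sensor noise (sd 6 intensity units) and 8-bit
  clipping.

`generate_growth_series()` wraps this in the paired-coupon experimental
design: exposure times 0/48/72/144 h, triplicates, suspension OD growing
exponentially by two decades from 0.006 AU with lognormal replicate noise
(sdlog 0.2), and growth level mapped affinely from log10 areal density
over the range 6.2–8.6 (chosen to bracket the densities the OD model
actually produces, so no sample degenerates to a featureless coupon).
Under these defaults the generator reproduces the qualitative behavior the
method is designed around, as verified by the test suite: BGI rises
monotonically in growth on every channel across seeds at roughly 13–15
points per decade of cell density with triplicate sds of a few points,
while binary Otsu coverage starts high and noisy on early-stage images
(texture-driven, sd ~10) and consequently ranks below BGI in at least
95 % of seeded replicate experiments.

### What the generator does not emulate

Lens and illumination gradients, white-balance drift, specular glints,
coupon misalignment, mounting-hole artifacts, and any mechanistic biofilm
physics (nutrient fields, detachment). Passing tests therefore demonstrate
the *algorithmic* contract — exact thresholding, score behavior, and the
statistical ranking machinery — under controlled image statistics, not
performance on any particular camera or organism.

### A note on featureless images

A coupon with no stain contrast at all (uniform tint plus symmetric noise)
scores near mid-scale: the eleven adaptive classes simply partition the
noise, and the mean ramp weight of a symmetric histogram is about one
half. BGI is informative for coupons with *any* visible staining — the
generator's operating range — and the degenerate direct mapping covers the
exactly-uniform limit. This is an inherent property of self-normalizing
multilevel thresholding, shared by the original method.

## Numerical choices and problem sizes

Exact integer thresholds in $[0, 254]$; all optimization is over the
256-bin histogram, so cost is independent of image size beyond the
histogram pass ($O(N \cdot 256^2)$ dynamic program, ~0.1 s). Test-suite
problem sizes were chosen for stable histograms at interactive cost:
120–160 px coupons for property checks, 16-level sparse histograms for
brute-force oracle comparisons (where exhaustive enumeration is exact),
and 100-replicate series for the ranking experiment.

## Limitations

* BGI is a relative, self-normalized score; comparing absolute values
  across very different substrates or lighting setups requires consistent
  photography, as with the original assay.
* The 0–1 AU proportionality of the OD control is taken as given; above
  1 AU the conversion warns rather than corrects.
* The manual-range comparator's range is user-supplied; no attempt is made
  to optimize it.
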