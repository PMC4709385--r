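# bgiscore

Quantify biofilm growth on stained sample coupons from ordinary digital
photographs.

Early surface fouling is hard to measure: confocal methods are slow and
local, and classical binary thresholding of photographs (Otsu or a manual
cut, reported as percent areal coverage) fails on the subtle, graded
darkening that early biofilms produce. `bgiscore` implements the **Biofilm
Growth Intensity (BGI)** score for this problem, together with the
comparator binary methods, the optical-density control calibration, and
the statistic used to rank image metrics against independently measured
cell density. It is aimed at microbiologists and biofouling researchers
running stain-photograph-score assays, and at anyone benchmarking
image-based biofilm metrics.

## The score

For one channel of a photograph over a region of interest, the 256-bin
intensity histogram is split into N + 1 classes (default N = 10 thresholds,
11 groups) by exact multilevel Otsu thresholding — the threshold vector
minimizing count-weighted within-class variance, found by dynamic
programming. A linear ramp filter weights each class from 0 (brightest) to
1 (darkest), giving the filtered histogram area

    A2 = sum_g w_g * count_g,   w_g linear from 0 to 1 toward darkness

and the score

    BGI = 100 * A2 / A1,        A1 = total pixel count.

BGI = 100 means every pixel is in the darkest threshold group; 0 means
every pixel is in the brightest. Unlike areal coverage, BGI responds to
the density and thickness of fouling, not just its extent.

The control arm converts OD600 readings of sonicated-off biofilm to areal
cell density (3.9e8 cells/mL per AU; cells × volume / colonized area), and
methods are ranked by `r * m` — Pearson correlation times min-max
normalized regression slope against log10 cell density, a 0–1 figure of
merit.

## Worked example

Everything below runs without any real photographs: the package ships a
synthetic generator that emulates stained, green-tinted fiberglass coupons
with growth-dependent fouling and a paired OD600 control.

```r
library(bgiscore)

img <- generate_coupon_image(coupon_growth_params(0.7, seed = 1),
                             size = c(200, 200))
analyze_image(img, roi(10, 190, 10, 190))
#> <bgi_report> synthetic coupon (growth 0.700, seed 1) (A1 = 32400 px)
#>   gray  BGI =  59.80
#>   red   BGI =  56.55
#>   green BGI =  59.65
#>   blue  BGI =  57.54
```

A heavily fouled coupon (growth 0.7 on a 0–1 scale) scores around 60 on
every channel; the red and blue channels sit slightly lower because the
purple-hued stain saturates them first. A clean coupon scores near the
bottom of the scale.

Full benchmarking workflow — generate a 4-time-point triplicate growth
series, score it with BGI and binary Otsu coverage, and rank both against
the cell-density control:

```r
dir <- tempfile()
write_growth_series(growth_series_spec(seed = 1), dir)   # 12 PNGs + CSVs

cmp <- compare_methods(file.path(dir, "manifest.csv"),
                       methods = c("bgi", "otsu"),
                       channels = c("gray", "green"))
rank_from_tables(cmp, file.path(dir, "control.csv"))
#>   rank     method     r     m score
#> 1    1   bgi/gray 0.940 0.955 0.898
#> 2    2  bgi/green 0.904 0.907 0.820
#> 3    3 otsu/green 0.727 0.674 0.490
#> 4    4  otsu/gray 0.714 0.629 0.449
```

BGI tracks log cell density tightly (r ≈ 0.94, near-unit slope), while
binary Otsu coverage — confused by substrate texture on early-stage
coupons and saturating late — fits far worse. This is the method's core
claim, and the test suite verifies it across 100 seeded replicate
experiments.

See `vignettes/bgi-methods.Rmd` for the model, conventions (threshold
class membership, tie-breaking, ramp spacing, degenerate images), the
generator's design and its limits.

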