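Package: bgiscore
Title: Biofilm Growth Intensity Scoring from Stained-Coupon Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies biofilm growth on stained sample coupons from
    ordinary digital photographs. Implements the Biofilm Growth Intensity
    (BGI) score, a 0-100 measure obtained by exact multilevel Otsu
    thresholding of a channel histogram followed by a linear ramp filter
    that weights dark (heavily fouled) pixel classes, together with the
    binary-thresholding comparators (Otsu and manual-range areal
    coverage), conversion of optical-density control measurements to
    areal cell densities, and the correlation-times-slope statistic used
    to rank image-analysis methods against an independent cell-density
    control. A synthetic coupon-image generator produces stained-coupon
    photographs with controllable growth so the whole pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
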