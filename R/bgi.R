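# Biofilm Growth Intensity: ramp-filtered histogram scoring ----------------

#' Linear ramp weights over threshold classes
#'
#' One weight per class, ordered brightest class to darkest class, rising
#' linearly from 0 to 1: the brightest (clean-substrate) class is discarded
#' and the darkest (thickest-biofilm) class counts fully, so the filtered
#' histogram area measures how dark — how fouled — the image is overall.
#'
#' The default spacing is `g / N` for classes `g = 0..N` (N = 10 gives 0,
#' 0.1, ..., 1.0), which is the unique equal spacing consistent with the
#' score's defining endpoints (all-brightest = 0, all-darkest = 100). Passing
#' `denominator = n_classes` reproduces the alternative reading in which
#' interior weights step by `1/(N+1)` while the last class still carries
#' weight 1.
#'
#' @param n_classes Number of classes N + 1 (>= 2).
#' @param denominator Spacing denominator; default `n_classes - 1` (equal
#'   spacing). Must be at least `n_classes - 1`.
#' @return Numeric vector of `n_classes` weights, brightest first, first
#'   weight 0, last weight 1, strictly increasing.
#' @examples
#' ramp_weights(11)      # 0, 0.1, ..., 1
#' ramp_weights(11, 11)  # 0, 1/11, ..., 9/11, 1
#' @export
ramp_weights <- function(n_classes, denominator = n_classes - 1L) {
  if (length(n_classes) != 1L || n_classes < 2L ||
      n_classes != round(n_classes))
    stop("`n_classes` must be an integer >= 2", call. = FALSE)
  if (denominator < n_classes - 1L)
    stop("`denominator` must be >= n_classes - 1 for strictly increasing ",
         "weights", call. = FALSE)
  w <- (seq_len(n_classes) - 1) / denominator
  w[n_classes] <- 1
  w
}

#' Apply a ramp filter to per-class pixel counts
#'
#' Computes the filtered histogram area A2: each class count is multiplied by
#' its ramp weight and the products summed. The filter is linear in the
#' counts, so it introduces no nonlinear distortion of the growth trend.
#'
#' @param class_counts Nonnegative pixel counts per class, ordered brightest
#'   class to darkest class (matching [ramp_weights()]).
#' @param weights Ramp weights from [ramp_weights()]; same length as
#'   `class_counts`.
#' @return The filtered area A2 (a scalar, at most `sum(class_counts)`).
#' @examples
#' ramp_filter(rep(10, 11), ramp_weights(11))  # 55
#' @export
ramp_filter <- function(class_counts, weights) {
  if (length(class_counts) != length(weights))
    stop("`class_counts` and `weights` must have equal length",
         call. = FALSE)
  if (anyNA(class_counts) || any(class_counts < 0))
    stop("class counts must be nonnegative", call. = FALSE)
  sum(weights * class_counts)
}

# Full per-channel BGI computation; returns intermediates for reporting.
.bgi_detail <- function(img, n_thresholds = 10L, thresholds = NULL,
                        ramp_denominator = NULL) {
  stopifnot(is_raster_image(img))
  if (img$channels != 1L)
    stop("BGI is computed per channel; pass a 1-channel image",
         call. = FALSE)
  hist <- compute_histogram(img)
  distinct <- sum(hist$counts > 0L)

  if (is.null(thresholds)) {
    if (distinct == 1L) {
      # uniform image: no threshold exists; score by direct intensity
      # mapping so blank (bright) and saturated (dark) coupons stay on the
      # 0..100 scale continuously
      v <- which(hist$counts > 0L) - 1L
      return(list(bgi = 100 * (255 - v) / 255, thresholds = NULL,
                  class_counts = NULL, a1 = hist$total, a2 = NA_real_,
                  degenerate = TRUE))
    }
    # near-degenerate images (d occupied levels, d <= N) cannot support N
    # thresholds; reduce to d - 1 so every occupied level gets its own class
    n_eff <- min(as.integer(n_thresholds), distinct - 1L)
    thresholds <- multilevel_otsu(hist, n_eff)
  } else if (!inherits(thresholds, "threshold_set")) {
    stop("`thresholds` must be a threshold_set", call. = FALSE)
  }

  q <- quantize(img, thresholds)
  n <- q$n_classes
  denom <- if (is.null(ramp_denominator)) n - 1L else ramp_denominator
  w <- ramp_weights(n, denom)
  # class_counts are intensity-ordered (class 0 darkest); ramp weights are
  # brightest-first, so reverse before weighting: darkest class gets 1
  a2 <- ramp_filter(rev(q$class_counts), w)
  a1 <- hist$total
  list(bgi = 100 * a2 / a1, thresholds = thresholds,
       class_counts = q$class_counts, a1 = a1, a2 = a2, degenerate = FALSE)
}

#' Compute the Biofilm Growth Intensity of a 1-channel image
#'
#' BGI scores an image between 0 and 100: the channel histogram is divided
#' into `n_thresholds + 1` classes by exact multilevel Otsu thresholding, a
#' linear ramp filter weights each class from 0 (brightest class) to 1
#' (darkest class), and the score is `100 * A2 / A1` where A2 is the
#' ramp-filtered histogram area and A1 the total pixel count. A score of 100
#' means every pixel sits in the darkest threshold group (heavy, dense
#' fouling); 0 means every pixel sits in the brightest group (clean
#' substrate). Unlike areal coverage, BGI responds to the density and
#' thickness of surface growth, not just its extent.
#'
#' A uniform (single-intensity) image cannot be thresholded and is scored by
#' the direct mapping `100 * (255 - v) / 255`; an image with `d <=
#' n_thresholds` occupied intensity levels is scored with `d - 1` thresholds
#' (each occupied level its own class).
#'
#' @param img A 1-channel [raster_image].
#' @param n_thresholds Number of thresholds (default 10, giving 11 groups).
#' @param thresholds Optional fixed [threshold_set] to use instead of
#'   computing multilevel Otsu thresholds from the image's own histogram
#'   (e.g. to share thresholds across images).
#' @param ramp_denominator Optional ramp-weight spacing denominator; see
#'   [ramp_weights()].
#' @return The BGI score, a number in \[0, 100\].
#' @examples
#' img <- raster_image(matrix(c(0L, 255L), 10, 10))
#' compute_bgi(img)  # 50: half the pixels in the darkest class
#' @export
compute_bgi <- function(img, n_thresholds = 10L, thresholds = NULL,
                        ramp_denominator = NULL) {
  .bgi_detail(img, n_thresholds, thresholds, ramp_denominator)$bgi
}

#' Score a coupon photograph on all channels
#'
#' Runs the BGI algorithm on the grayscale conversion and on each color
#' channel of a photograph over a region of interest. Each channel's
#' histogram is thresholded independently, since the stain components
#' respond differently per channel. The retained intermediates (thresholds,
#' class counts, A1/A2) allow export of the stretched images and full
#' reports.
#'
#' @param img A [raster_image] (3-channel; a 1-channel image is scored as
#'   gray only).
#' @param region A [roi] or `NULL` for the full image.
#' @param n_thresholds Number of thresholds per channel (default 10).
#' @param channels Subset of `c("gray", "red", "green", "blue")` to score.
#' @param gray_weights Grayscale conversion weights; see [to_grayscale()].
#' @param ramp_denominator See [ramp_weights()].
#' @return An object of class `bgi_report`: per-channel entries (each with
#'   `bgi`, `thresholds`, `class_counts`, `a1`, `a2`), plus the analysis
#'   settings.
#' @export
analyze_image <- function(img, region = NULL, n_thresholds = 10L,
                          channels = c("gray", "red", "green", "blue"),
                          gray_weights = c("luma", "equal"),
                          ramp_denominator = NULL) {
  stopifnot(is_raster_image(img))
  gray_weights <- match.arg(gray_weights)
  channels <- match.arg(channels, several.ok = TRUE)
  sub <- extract_roi(img, region)
  if (sub$channels == 1L) {
    planes <- list(gray = sub)
    channels <- "gray"
  } else {
    planes <- c(list(gray = to_grayscale(sub, gray_weights)),
                split_channels(sub))
  }
  res <- lapply(channels, function(ch)
    .bgi_detail(planes[[ch]], n_thresholds,
                ramp_denominator = ramp_denominator))
  names(res) <- channels
  structure(
    list(channels = res, a1 = sub$height * sub$width, roi = region,
         n_thresholds = as.integer(n_thresholds),
         gray_weights = gray_weights,
         ramp_denominator = ramp_denominator,
         provenance = img$provenance),
    class = "bgi_report")
}

#' @export
print.bgi_report <- function(x, ...) {
  cat(sprintf("<bgi_report> %s (A1 = %d px)\n", x$provenance, x$a1))
  for (ch in names(x$channels)) {
    d <- x$channels[[ch]]
    cat(sprintf("  %-5s BGI = %6.2f%s\n", ch, d$bgi,
                if (isTRUE(d$degenerate)) "  (uniform image)" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.bgi_report <- function(x, ...) {
  do.call(rbind, lapply(names(x$channels), function(ch) {
    d <- x$channels[[ch]]
    data.frame(channel = ch, bgi = d$bgi, a1 = d$a1, a2 = d$a2,
               n_thresholds = x$n_thresholds, stringsAsFactors = FALSE)
  }))
}
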