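# Binary/multilevel Otsu thresholding, quantization, areal coverage --------

#' Construct a threshold set
#'
#' N strictly increasing integer levels in \[0, 254\] partitioning \[0, 255\]
#' into N + 1 classes. A pixel of intensity v with threshold t satisfies
#' "v <= t goes to the lower class", so class g is the number of levels
#' strictly below v's position: class 0 collects the darkest intensities.
#'
#' @param levels Strictly increasing integer vector, each in \[0, 254\].
#' @return An object of class `threshold_set` with fields `levels` and
#'   `n_classes` (= N + 1).
#' @examples
#' threshold_set(c(50, 120, 200))
#' @export
threshold_set <- function(levels) {
  if (length(levels) < 1L || anyNA(levels) || any(levels != round(levels)))
    stop("`levels` must be one or more integers", call. = FALSE)
  if (any(levels < 0) || any(levels > 254))
    stop("threshold levels must lie in [0, 254]", call. = FALSE)
  if (any(diff(levels) <= 0))
    stop("threshold levels must be strictly increasing", call. = FALSE)
  structure(list(levels = as.integer(levels),
                 n_classes = length(levels) + 1L),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %d thresholds -> %d classes: %s\n",
              length(x$levels), x$n_classes,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

as_histogram <- function(hist) {
  if (inherits(hist, "channel_histogram")) return(hist)
  if (is_raster_image(hist)) return(compute_histogram(hist))
  stop("expected a channel_histogram or 1-channel raster_image",
       call. = FALSE)
}

# Between-class objective for bins lo..hi (1-based over 256 bins) given
# cumulative count P and cumulative count*intensity S. Maximizing the sum of
# S_g^2 / W_g over classes is algebraically equivalent to minimizing the
# count-weighted within-class variance.
.class_gain <- function(P, S, lo, hi) {
  P0 <- c(0, P)
  S0 <- c(0, S)
  w <- P[hi] - P0[lo]
  s <- S[hi] - S0[lo]
  ifelse(w > 0, s * s / w, 0)
}

#' Binary Otsu threshold
#'
#' Finds the single threshold t in \[0, 254\] minimizing the count-weighted
#' sum of within-class intensity variances (equivalently maximizing
#' between-class variance). Ties are broken toward the smallest t.
#'
#' @param hist A `channel_histogram` (or a 1-channel [raster_image], whose
#'   histogram is computed first).
#' @return A [threshold_set] with a single level.
#' @examples
#' h <- channel_histogram(tabulate(c(rep(1, 50), rep(256, 50)), 256))
#' otsu_binary_threshold(h)$levels  # 0: any cut separates the two spikes
#' @export
otsu_binary_threshold <- function(hist) {
  hist <- as_histogram(hist)
  if (sum(hist$counts > 0L) < 2L)
    stop("degenerate histogram: need at least two occupied intensity ",
         "levels to threshold", call. = FALSE)
  P <- cumsum(hist$counts)
  S <- cumsum(hist$counts * (0:255))
  # candidate t = 0..254 puts bins 1..(t+1) in the lower class
  j <- 1:255
  obj <- .class_gain(P, S, 1L, j) + .class_gain(P, S, j + 1L, 256L)
  t_best <- which.max(obj) - 1L  # which.max takes the first (smallest) max
  threshold_set(t_best)
}

#' Multilevel Otsu thresholding by exact dynamic programming
#'
#' Generalizes Otsu's method to `n_thresholds` levels dividing the 256-bin
#' histogram into `n_thresholds + 1` classes so that the total count-weighted
#' within-class variance is minimized. The optimum is found exactly by
#' dynamic programming over cumulative count and count-times-intensity sums
#' (no stochastic search), and ties are broken toward the lexicographically
#' lowest threshold vector. With the default `n_thresholds = 10` the image is
#' divided into 11 groups.
#'
#' @param hist A `channel_histogram` (or a 1-channel [raster_image]).
#' @param n_thresholds Number of thresholds N >= 1 (default 10).
#' @return A [threshold_set] with `n_thresholds` levels.
#' @export
multilevel_otsu <- function(hist, n_thresholds = 10L) {
  hist <- as_histogram(hist)
  if (length(n_thresholds) != 1L || is.na(n_thresholds) ||
      n_thresholds != round(n_thresholds) || n_thresholds < 1L)
    stop("`n_thresholds` must be a positive integer", call. = FALSE)
  n_thresholds <- as.integer(n_thresholds)
  if (sum(hist$counts > 0L) <= n_thresholds)
    stop("degenerate histogram: need more occupied intensity levels (",
         sum(hist$counts > 0L), ") than thresholds (", n_thresholds, ")",
         call. = FALSE)

  P <- cumsum(hist$counts)
  S <- cumsum(hist$counts * (0:255))
  K <- n_thresholds + 1L  # classes

  # G[k, i]: best objective for bins i..256 split into k classes. Suffix
  # formulation so ties can be resolved left-to-right into the
  # lexicographically smallest threshold vector.
  G <- matrix(-Inf, nrow = K, ncol = 257L)
  G[1L, 1:256] <- .class_gain(P, S, 1:256, 256L)
  for (k in 2:K) {
    # class starting at bin i may end at b = i..(256 - k + 1)
    for (i in 1:(256L - k + 1L)) {
      b <- i:(256L - k + 1L)
      G[k, i] <- max(.class_gain(P, S, i, b) + G[k - 1L, b + 1L])
    }
  }

  levels <- integer(n_thresholds)
  i <- 1L
  for (k in K:2L) {
    b <- i:(256L - k + 1L)
    cand <- .class_gain(P, S, i, b) + G[k - 1L, b + 1L]
    split <- b[which.max(cand)]  # first max -> smallest boundary
    levels[K - k + 1L] <- split - 1L  # bin index -> threshold intensity
    i <- split + 1L
  }
  threshold_set(levels)
}

#' Quantize an image into threshold classes with contrast stretch
#'
#' Assigns each pixel its class index (0 = darkest) under a [threshold_set]
#' and records the display stretch map that spreads the N + 1 class indices
#' over the full 0..255 range (class g maps to `round(g * 255 / N)`),
#' enhancing contrast in the rendered image.
#'
#' @param img A 1-channel [raster_image].
#' @param thresholds A [threshold_set].
#' @return An object of class `quantized_image` with fields `class_map`
#'   (integer matrix), `n_classes`, `stretch_map` (intensity per class) and
#'   `class_counts` (pixels per class).
#' @export
quantize <- function(img, thresholds) {
  stopifnot(is_raster_image(img), inherits(thresholds, "threshold_set"))
  if (img$channels != 1L)
    stop("quantize() requires a 1-channel image", call. = FALSE)
  v <- img$pixels[, , 1L]
  # v <= t -> lower class, so class = number of levels strictly below v
  cm <- matrix(findInterval(v, thresholds$levels + 0.5), nrow(v), ncol(v))
  storage.mode(cm) <- "integer"
  n <- thresholds$n_classes
  structure(
    list(class_map = cm, n_classes = n,
         stretch_map = as.integer(round((0:(n - 1L)) * 255 / (n - 1L))),
         class_counts = tabulate(cm + 1L, nbins = n),
         thresholds = thresholds),
    class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %d x %d px, %d classes\n",
              nrow(x$class_map), ncol(x$class_map), x$n_classes))
  cat("  class counts:", paste(x$class_counts, collapse = " "), "\n")
  invisible(x)
}

#' Render a quantized image as a contrast-stretched raster image
#'
#' @param q A `quantized_image`.
#' @return A 1-channel [raster_image] where class g has intensity
#'   `round(g * 255 / N)`.
#' @export
stretch_image <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  px <- matrix(q$stretch_map[q$class_map + 1L],
               nrow(q$class_map), ncol(q$class_map))
  raster_image(px, provenance = "stretched quantized image")
}

#' Manual-range thresholding
#'
#' Marks pixels with intensity in the closed range `[low, high]` as
#' foreground (biofilm) and everything else background, the manually selected
#' threshold-range comparator to Otsu's method.
#'
#' @param x A 1-channel [raster_image] (returns a logical foreground mask) or
#'   a `channel_histogram` (returns a `binary_summary` holding foreground and
#'   total counts, enough for [areal_coverage()]).
#' @param low,high Intensity bounds, `0 <= low <= high <= 255`.
#' @return A logical matrix mask, or a `binary_summary`.
#' @export
manual_threshold <- function(x, low, high) {
  if (anyNA(c(low, high)) || low < 0 || high > 255 || low > high)
    stop("need 0 <= low <= high <= 255", call. = FALSE)
  if (is_raster_image(x)) {
    if (x$channels != 1L)
      stop("manual_threshold() requires a 1-channel image", call. = FALSE)
    v <- x$pixels[, , 1L]
    return(v >= low & v <= high)
  }
  if (inherits(x, "channel_histogram")) {
    fg <- sum(x$counts[(low + 1L):(high + 1L)])
    return(structure(list(foreground = fg, total = x$total),
                     class = "binary_summary"))
  }
  stop("`x` must be a 1-channel raster_image or channel_histogram",
       call. = FALSE)
}

#' Areal coverage of a binary segmentation
#'
#' The percentage of pixels classified as foreground (biofilm): the quantity
#' both binary comparator methods report.
#'
#' @param x A logical foreground mask (from [manual_threshold()]), a
#'   `binary_summary`, or a 2-class `quantized_image` from a binary Otsu
#'   threshold, whose dark class (class 0, the stained pixels) counts as
#'   foreground.
#' @return Coverage percentage in \[0, 100\].
#' @examples
#' areal_coverage(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))  # 25
#' @export
areal_coverage <- function(x) {
  if (is.logical(x) && is.matrix(x)) {
    if (length(x) == 0L) stop("empty mask", call. = FALSE)
    return(100 * sum(x) / length(x))
  }
  if (inherits(x, "binary_summary")) {
    if (x$total == 0L) stop("empty histogram", call. = FALSE)
    return(100 * x$foreground / x$total)
  }
  if (inherits(x, "quantized_image")) {
    if (x$n_classes != 2L)
      stop("areal coverage needs a binary (2-class) quantization",
           call. = FALSE)
    return(100 * x$class_counts[1L] / sum(x$class_counts))
  }
  stop("`x` must be a logical mask, binary_summary or 2-class ",
       "quantized_image", call. = FALSE)
}

#' Otsu areal coverage of a 1-channel image
#'
#' Convenience composition of [otsu_binary_threshold()], [quantize()] and
#' [areal_coverage()]: the classical binary-thresholding biofilm measure.
#'
#' @param img A 1-channel [raster_image].
#' @return Coverage percentage of the dark (foreground) class.
#' @export
otsu_coverage <- function(img) {
  areal_coverage(quantize(img, otsu_binary_threshold(img)))
}
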