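# OD600 control conversion and method-ranking statistics -------------------

#' Convert optical density to suspended cell concentration
#'
#' In the 0-1 AU range, optical density at 600 nm is roughly proportional to
#' cell density at 3.9e8 cells per mL per absorbance unit; above 1 AU the
#' proportionality degrades and a warning is issued.
#'
#' @param od600 Absorbance at 600 nm (AU), nonnegative.
#' @param cells_per_au Proportionality constant (cells mL^-1 AU^-1).
#' @return Cell concentration in cells per mL.
#' @examples
#' od_to_cell_concentration(1.0)  # 3.9e8
#' @export
od_to_cell_concentration <- function(od600, cells_per_au = 3.9e8) {
  if (anyNA(od600) || any(od600 < 0))
    stop("`od600` must be nonnegative", call. = FALSE)
  if (any(od600 > 1))
    warning("OD600 above 1 AU: proportionality to cell density degrades ",
            "outside the 0-1 AU range", call. = FALSE)
  cells_per_au * od600
}

#' Record an optical-density control measurement
#'
#' Captures the geometry of the control assay: biofilm is sonicated off a
#' square coupon into a known suspension volume and the suspension's OD600 is
#' measured, so the areal density can be reconstructed over the coupon's
#' faces.
#'
#' @param od600 Absorbance at 600 nm (AU).
#' @param suspension_volume Suspension volume in mL (default 15).
#' @param coupon_side Coupon side length in cm (default 2.5).
#' @param n_sides Number of colonized faces counted (default 2).
#' @return An object of class `od_measurement`.
#' @export
od_measurement <- function(od600, suspension_volume = 15,
                           coupon_side = 2.5, n_sides = 2L) {
  if (anyNA(od600) || any(od600 < 0))
    stop("`od600` must be nonnegative", call. = FALSE)
  if (suspension_volume <= 0) stop("volume must be positive", call. = FALSE)
  if (coupon_side <= 0) stop("side length must be positive", call. = FALSE)
  if (n_sides < 1) stop("`n_sides` must be >= 1", call. = FALSE)
  structure(list(od600 = od600, suspension_volume = suspension_volume,
                 coupon_side = coupon_side, n_sides = as.integer(n_sides)),
            class = "od_measurement")
}

#' Areal cell density of a coupon from its control measurement
#'
#' Total dispersed cells (concentration times suspension volume) divided by
#' the colonized area (`n_sides * coupon_side^2`): the independent control
#' against which every image-analysis metric is ranked.
#'
#' @param m An [od_measurement()], or a numeric OD600 value used with the
#'   default assay geometry.
#' @param ... Passed to [od_measurement()] when `m` is numeric.
#' @param cells_per_au See [od_to_cell_concentration()].
#' @return Areal density in cells per cm^2.
#' @examples
#' areal_cell_density(1.0)  # 3.9e8 * 15 / 12.5 = 4.68e8
#' @export
areal_cell_density <- function(m, ..., cells_per_au = 3.9e8) {
  if (is.numeric(m)) m <- od_measurement(m, ...)
  if (!inherits(m, "od_measurement"))
    stop("`m` must be an od_measurement or numeric OD600", call. = FALSE)
  area <- m$n_sides * m$coupon_side^2
  od_to_cell_concentration(m$od600, cells_per_au) * m$suspension_volume / area
}

assert_series_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 paired samples", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("series contain NA", call. = FALSE)
}

#' Pearson product-moment correlation between two series
#'
#' @param x,y Equal-length numeric series (length >= 3), neither constant.
#' @return The correlation coefficient r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  assert_series_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

minmax_normalize <- function(x) {
  r <- range(x)
  if (r[1L] == r[2L])
    stop("cannot min-max normalize a constant series", call. = FALSE)
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Slope of a simple linear regression on min-max normalized scales
#'
#' Both series are rescaled to \[0, 1\] before the ordinary-least-squares
#' fit, so "slope nearest 1" is meaningful even when the metric and the
#' control carry different units (score points vs cells cm^-2).
#'
#' @param x Predictor series (the control).
#' @param y Response series (the image metric).
#' @param normalize Min-max normalize both series first (default TRUE).
#' @return The OLS slope m.
#' @export
regression_slope <- function(x, y, normalize = TRUE) {
  assert_series_pair(x, y)
  if (stats::sd(x) == 0)
    stop("slope undefined for a constant predictor", call. = FALSE)
  if (normalize) {
    x <- minmax_normalize(x)
    y <- minmax_normalize(y)
  }
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Log-transform a cell-density control series
#'
#' Cell density grows over orders of magnitude while image scores are
#' linear, so the control is log10-transformed before correlation and
#' regression. Zero-density samples are mapped to the assay floor, one count
#' below the minimum observed positive density.
#'
#' @param density Areal densities (cells cm^-2), nonnegative.
#' @return log10 densities.
#' @export
log_transform_control <- function(density) {
  if (anyNA(density) || any(density < 0))
    stop("densities must be nonnegative", call. = FALSE)
  pos <- density[density > 0]
  if (length(pos) == 0L)
    stop("all control densities are zero; nothing to transform",
         call. = FALSE)
  floor_val <- max(min(pos) - 1, .Machine$double.xmin)
  log10(ifelse(density > 0, density, floor_val))
}

#' Goodness of fit between an image metric and the cell-density control
#'
#' Computes the Pearson correlation r and the normalized regression slope m
#' of the metric against the (by default log10-transformed) control, and
#' combines them into the single best-fit measure `score = r * m`, clamped
#' to \[0, 1\]: both r and m must be near 1 for a method to rank well.
#' Because both series enter the same least-squares fit, r and m always
#' share a sign and their raw product is nonnegative even for a metric
#' that tracks the control inversely; anti-correlated metrics (negative r)
#' are therefore floored at 0 directly, which is what confining the
#' measure to the 0-1 scale is for.
#'
#' @param values Image-metric value per sample (e.g. BGI or coverage).
#' @param control Paired areal cell density per sample (cells cm^-2).
#' @param label Method label used in rankings.
#' @param log_control log10-transform the control first (default TRUE).
#' @return An object of class `method_fit` with fields `label`, `r`, `m`,
#'   `score`.
#' @export
fit_score <- function(values, control, label = "method",
                      log_control = TRUE) {
  assert_series_pair(values, control)
  ctrl <- if (log_control) log_transform_control(control) else control
  r <- pearson_r(ctrl, values)
  m <- regression_slope(ctrl, values)
  score <- if (r < 0 || m < 0) 0 else min(r * m, 1)
  structure(list(label = as.character(label)[1L], r = r, m = m,
                 score = score),
            class = "method_fit")
}

#' @export
print.method_fit <- function(x, ...) {
  cat(sprintf("<method_fit> %s: r = %.3f, m = %.3f, score = %.3f\n",
              x$label, x$r, x$m, x$score))
  invisible(x)
}

#' Rank image-analysis methods by fit against the control
#'
#' @param fits A list of `method_fit` objects (length >= 2).
#' @return A data frame with columns `rank`, `method`, `r`, `m`, `score`,
#'   ordered best to worst score; ties broken alphabetically by label.
#' @export
rank_methods <- function(fits) {
  if (length(fits) < 2L)
    stop("need at least two method fits to rank", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1L), "method_fit")))
    stop("`fits` must be a list of method_fit objects", call. = FALSE)
  df <- data.frame(
    method = vapply(fits, `[[`, character(1L), "label"),
    r = vapply(fits, `[[`, numeric(1L), "r"),
    m = vapply(fits, `[[`, numeric(1L), "m"),
    score = vapply(fits, `[[`, numeric(1L), "score"),
    stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$method), , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}
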