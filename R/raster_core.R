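# Image containers, channel handling, ROI extraction and histograms --------

#' Construct a raster image
#'
#' The basic unit of analysis: a height x width grid of 8-bit integer
#' intensities with either 1 (gray) or 3 (red, green, blue) channels.
#'
#' @param pixels A matrix (1 channel) or a height x width x channels array of
#'   integer intensities in \[0, 255\]. Channels must be 1 or 3.
#' @param provenance Free-text label recording where the image came from.
#' @return An object of class `raster_image` with fields `pixels` (always a
#'   3-d integer array), `channels`, `height`, `width`, `provenance`.
#' @examples
#' img <- raster_image(matrix(0L, 4, 4))
#' dim(img)
#' @export
raster_image <- function(pixels, provenance = "in-memory") {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be a matrix or a 3-d array", call. = FALSE)
  ch <- dim(pixels)[3L]
  if (!ch %in% c(1L, 3L))
    stop("channel count must be 1 (gray) or 3 (rgb), got ", ch, call. = FALSE)
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels)) stop("intensities must not contain NA", call. = FALSE)
  if (any(pixels != round(pixels)))
    stop("intensities must be integers", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, channels = ch,
         height = dim(pixels)[1L], width = dim(pixels)[2L],
         provenance = as.character(provenance)[1L]),
    class = "raster_image")
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %d channel%s (%s)\n",
              x$height, x$width, x$channels, if (x$channels > 1) "s" else "",
              x$provenance))
  rng <- range(x$pixels)
  cat(sprintf("  intensity range [%d, %d]\n", rng[1L], rng[2L]))
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

#' Construct a rectangular region of interest
#'
#' Coordinates are 0-based and half-open (`[start, end)`), row-major, so a ROI
#' of `roi(0, h, 0, w)` covers the whole image. Analysis regions are given
#' explicitly (not interactively) so runs are reproducible; choose them to
#' exclude coupon edges, mounting holes and markings.
#'
#' @param row_start,row_end,col_start,col_end Pixel indices, 0-based,
#'   half-open.
#' @return An object of class `roi`.
#' @examples
#' roi(2, 5, 3, 7)  # rows 2..4, columns 3..6
#' @export
roi <- function(row_start, row_end, col_start, col_end) {
  v <- c(row_start, row_end, col_start, col_end)
  if (anyNA(v) || any(v != round(v)))
    stop("ROI coordinates must be integers", call. = FALSE)
  if (row_start < 0 || col_start < 0 || row_start >= row_end ||
      col_start >= col_end)
    stop("ROI must satisfy 0 <= start < end for rows and columns",
         call. = FALSE)
  structure(list(row_start = as.integer(row_start),
                 row_end = as.integer(row_end),
                 col_start = as.integer(col_start),
                 col_end = as.integer(col_end)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows [%d, %d), cols [%d, %d)\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

# Map a normalized [0,1] pixel array (as returned by png/tiff readers) to
# 8-bit integers. True 8-bit sources store k/255, i.e. round(v*65535) is a
# multiple of 257; anything else is treated as 16-bit and rescaled to 8 bit
# by integer division by 256.
normalized_to_8bit <- function(x) {
  k16 <- round(x * 65535)
  if (all(k16 %% 257 == 0)) k16 %/% 257L else k16 %/% 256L
}

drop_alpha <- function(px) {
  ch <- dim(px)[3L]
  if (ch == 2L) px[, , 1L, drop = FALSE]
  else if (ch == 4L) px[, , 1:3, drop = FALSE]
  else px
}

#' Load an image file as a raster image
#'
#' Reads PNG, TIFF or JPEG rasters. Alpha channels are dropped; 16-bit
#' sources are rescaled to 8-bit by integer division so every histogram has
#' 256 bins. Camera-native RAW formats are not decoded; convert upstream.
#'
#' @param path Path to a PNG (`.png`), TIFF (`.tif`/`.tiff`) or JPEG
#'   (`.jpg`/`.jpeg`) file. JPEG support requires the EBImage package.
#' @return A [raster_image] with 1 or 3 channels.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG decoding requires the EBImage package", call. = FALSE)
      e <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores width x height (x channels); transpose to row-major
      if (length(dim(e)) == 2L) t(e) else aperm(e, c(2L, 1L, 3L))
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  if (length(dim(px)) != 3L)
    stop("could not decode ", path, " as a 2-d raster", call. = FALSE)
  px <- drop_alpha(px)
  if (!dim(px)[3L] %in% c(1L, 3L))
    stop("unsupported channel count after alpha drop: ", dim(px)[3L],
         call. = FALSE)
  raster_image(normalized_to_8bit(px), provenance = path)
}

#' Write a raster image to a PNG file
#'
#' Companion to [load_image()]; used to export stretched or binary images for
#' visual inspection.
#'
#' @param img A [raster_image], or a logical matrix (written as a black
#'   foreground / white background mask).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.logical(img) && is.matrix(img)) {
    # foreground (TRUE) rendered black, matching stained-biofilm display
    img <- raster_image(matrix(ifelse(img, 0L, 255L), nrow(img), ncol(img)))
  }
  stopifnot(is_raster_image(img))
  arr <- img$pixels / 255
  if (img$channels == 1L) arr <- arr[, , 1L]
  png::writePNG(arr, path)
  invisible(path)
}

#' Convert a color image to grayscale
#'
#' Uses ITU-R BT.601 luma weights (0.299, 0.587, 0.114) by default, the
#' standard camera-pipeline convention for an overall average of the three
#' channels; `weights = "equal"` gives the plain mean instead. A 1-channel
#' image is returned unchanged.
#'
#' @param img A [raster_image].
#' @param weights `"luma"` (default) or `"equal"`.
#' @return A 1-channel [raster_image] of the same size.
#' @examples
#' px <- array(c(100L, 200L, 50L), c(1, 1, 3))
#' to_grayscale(raster_image(px))$pixels[1, 1, 1]  # 153
#' @export
to_grayscale <- function(img, weights = c("luma", "equal")) {
  stopifnot(is_raster_image(img))
  weights <- match.arg(weights)
  if (img$channels == 1L) return(img)
  w <- if (weights == "luma") c(0.299, 0.587, 0.114) else rep(1 / 3, 3)
  g <- w[1] * img$pixels[, , 1L] + w[2] * img$pixels[, , 2L] +
    w[3] * img$pixels[, , 3L]
  g <- matrix(pmin(pmax(round(g), 0), 255), img$height, img$width)
  raster_image(g, provenance = paste0(img$provenance, " [gray:", weights, "]"))
}

#' Split a color image into its red, green and blue channels
#'
#' Stain components respond differently per channel, so each channel is
#' scored separately; [merge_channels()] inverts the split exactly.
#'
#' @param img A 3-channel [raster_image].
#' @return A named list of three 1-channel [raster_image]s
#'   (`red`, `green`, `blue`).
#' @export
split_channels <- function(img) {
  stopifnot(is_raster_image(img))
  if (img$channels != 3L)
    stop("split_channels() requires a 3-channel image", call. = FALSE)
  one <- function(k, lab)
    raster_image(img$pixels[, , k],
                 provenance = paste0(img$provenance, " [", lab, "]"))
  list(red = one(1L, "red"), green = one(2L, "green"), blue = one(3L, "blue"))
}

#' Recombine red, green and blue channel images
#'
#' @param red,green,blue 1-channel [raster_image]s of identical size.
#' @return A 3-channel [raster_image].
#' @export
merge_channels <- function(red, green, blue) {
  stopifnot(is_raster_image(red), is_raster_image(green),
            is_raster_image(blue))
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue)))
    stop("channel images must have identical dimensions", call. = FALSE)
  px <- array(0L, c(red$height, red$width, 3L))
  px[, , 1L] <- red$pixels[, , 1L]
  px[, , 2L] <- green$pixels[, , 1L]
  px[, , 3L] <- blue$pixels[, , 1L]
  raster_image(px, provenance = "merged channels")
}

#' Extract a region of interest from an image
#'
#' @param img A [raster_image].
#' @param region A [roi]; must lie within the image. `NULL` returns the image
#'   unchanged (full-extent analysis).
#' @return The sub-image covering exactly the half-open index ranges.
#' @export
extract_roi <- function(img, region) {
  stopifnot(is_raster_image(img))
  if (is.null(region)) return(img)
  if (!inherits(region, "roi")) stop("`region` must be a roi", call. = FALSE)
  if (region$row_end > img$height || region$col_end > img$width)
    stop(sprintf("ROI [%d,%d)x[%d,%d) exceeds image extent %d x %d",
                 region$row_start, region$row_end, region$col_start,
                 region$col_end, img$height, img$width), call. = FALSE)
  rows <- (region$row_start + 1L):region$row_end
  cols <- (region$col_start + 1L):region$col_end
  raster_image(img$pixels[rows, cols, , drop = FALSE],
               provenance = paste0(img$provenance, " [roi]"))
}

#' Compute the 256-bin intensity histogram of a 1-channel image
#'
#' The histogram is the object all thresholding and scoring operates on; its
#' total is the A1 "area under the original histogram" (the ROI pixel count).
#'
#' @param img A 1-channel [raster_image].
#' @param channel_label One of `"gray"`, `"red"`, `"green"`, `"blue"`.
#' @return An object of class `channel_histogram` with fields `counts`
#'   (integer vector of length 256, bin k holds intensity k-1), `total`,
#'   `channel_label`.
#' @export
compute_histogram <- function(img, channel_label = "gray") {
  stopifnot(is_raster_image(img))
  if (img$channels != 1L)
    stop("compute_histogram() requires a 1-channel image; use ",
         "split_channels() or to_grayscale() first", call. = FALSE)
  channel_label <- match.arg(channel_label,
                             c("gray", "red", "green", "blue"))
  counts <- tabulate(as.vector(img$pixels) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts),
                 channel_label = channel_label),
            class = "channel_histogram")
}

#' Build a channel histogram directly from bin counts
#'
#' Mostly useful for testing threshold algorithms on constructed histograms.
#'
#' @param counts Nonnegative integer vector of length 256 (bin k = intensity
#'   k-1).
#' @param channel_label Channel name.
#' @return A `channel_histogram`.
#' @export
channel_histogram <- function(counts, channel_label = "gray") {
  if (length(counts) != 256L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("`counts` must be 256 nonnegative integers", call. = FALSE)
  channel_label <- match.arg(channel_label,
                             c("gray", "red", "green", "blue"))
  counts <- as.integer(counts)
  structure(list(counts = counts, total = sum(counts),
                 channel_label = channel_label),
            class = "channel_histogram")
}

#' @export
print.channel_histogram <- function(x, ...) {
  nz <- which(x$counts > 0L) - 1L
  cat(sprintf("<channel_histogram> %s: %d pixels, %d occupied levels [%d, %d]\n",
              x$channel_label, x$total, length(nz),
              if (length(nz)) min(nz) else NA, if (length(nz)) max(nz) else NA))
  invisible(x)
}
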