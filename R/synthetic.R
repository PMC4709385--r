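# Synthetic stained-coupon photographs and paired control series -----------

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Parameters for one synthetic stained-coupon photograph
#'
#' Describes a photograph of a square green-tinted fiberglass coupon after
#' staining: a lightly textured substrate overlaid with smooth, spatially
#' heterogeneous dark stain patches whose cumulative opacity grows with a
#' single dimensionless growth level, plus additive sensor noise.
#'
#' @param growth_level Dimensionless fouling level in \[0, 1\] controlling
#'   the darkness and extent of the stained patches.
#' @param substrate_tint RGB triple of the clean substrate (default a
#'   fiberglass green).
#' @param stain_tint RGB triple toward which stained pixels darken (default
#'   purple-hued, as for a mixed biomolecular stain).
#' @param blob_count Number of random stain patches.
#' @param blob_scale Patch length scale as a fraction of the coupon side.
#' @param noise_sd Gaussian sensor-noise standard deviation in intensity
#'   units.
#' @param stain_exponent Colony-onset exponent k in the opacity law
#'   `field^(k / growth_level)`; smaller values make fouling spread faster.
#' @param texture_depth Peak relative darkening of the substrate's weave
#'   shading (stain-enhanced texture shadows visible on uncovered
#'   substrate); 0 disables texture.
#' @param seed RNG seed; the image is a pure function of seed + parameters.
#' @return An object of class `coupon_growth_params`.
#' @export
coupon_growth_params <- function(growth_level,
                                 substrate_tint = c(140, 165, 125),
                                 stain_tint = c(95, 45, 110),
                                 blob_count = 40L,
                                 blob_scale = 0.15,
                                 noise_sd = 6,
                                 stain_exponent = 0.5,
                                 texture_depth = 0.22,
                                 seed = 1L) {
  if (length(growth_level) != 1L || is.na(growth_level) ||
      growth_level < 0 || growth_level > 1)
    stop("`growth_level` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  for (tint in list(substrate_tint, stain_tint))
    if (length(tint) != 3L || any(tint < 0) || any(tint > 255))
      stop("tints must be RGB triples in [0, 255]", call. = FALSE)
  if (blob_count < 1L) stop("`blob_count` must be >= 1", call. = FALSE)
  if (blob_scale <= 0) stop("`blob_scale` must be positive", call. = FALSE)
  if (stain_exponent <= 0)
    stop("`stain_exponent` must be positive", call. = FALSE)
  if (texture_depth < 0 || texture_depth >= 1)
    stop("`texture_depth` must lie in [0, 1)", call. = FALSE)
  structure(list(growth_level = growth_level,
                 substrate_tint = substrate_tint,
                 stain_tint = stain_tint,
                 blob_count = as.integer(blob_count),
                 blob_scale = blob_scale,
                 noise_sd = noise_sd,
                 stain_exponent = stain_exponent,
                 texture_depth = texture_depth,
                 seed = as.integer(seed)),
            class = "coupon_growth_params")
}

# Smooth random field in [0, 1]: a sum of separable Gaussian bumps with
# random centers, amplitudes and widths, min-max normalized so some clean
# substrate always remains at field value 0.
.blob_field <- function(h, w, blob_count, blob_scale) {
  ys <- (seq_len(h) - 0.5) / h
  xs <- (seq_len(w) - 0.5) / w
  cy <- stats::runif(blob_count)
  cx <- stats::runif(blob_count)
  amp <- stats::runif(blob_count, 0.4, 1)
  sig <- blob_scale * stats::runif(blob_count, 0.5, 1.5)
  f <- matrix(0, h, w)
  for (i in seq_len(blob_count)) {
    ry <- exp(-(ys - cy[i])^2 / (2 * sig[i]^2))
    rx <- exp(-(xs - cx[i])^2 / (2 * sig[i]^2))
    f <- f + amp[i] * (ry %o% rx)
  }
  r <- range(f)
  if (r[1L] == r[2L]) matrix(0, h, w) else (f - r[1L]) / (r[2L] - r[1L])
}

#' Generate a synthetic stained-coupon photograph
#'
#' Stained biofilm is laid over the substrate as an opacity field
#' `opacity = depth(g) * field^(stain_exponent / g)` (g = growth level)
#' where `field` is a smooth random patch field in \[0, 1\]: colonies
#' nucleate at the field's maxima, then spread outward and deepen as the
#' growth level rises, while low-field substrate stays clean (a persistent
#' bright remnant). The depth factor `min(1, 0.45 + 0.55 g / 0.4)` keeps
#' early films subtle and graded rather than saturated. Opacity is
#' strictly nondecreasing in `growth_level` at every pixel, and
#' `growth_level = 0` gives a perfectly clean coupon. The stain is
#' composited multiplicatively — a pixel with opacity `o` becomes
#' `substrate * (1 - o * (1 - stain/255))` per channel — so channels the
#' stain absorbs strongly (red and blue under a purple-hued stain) darken
#' toward saturation first.
#'
#' Exposed substrate additionally carries broad weave shading — texture
#' shadows that stain residue makes visible as soon as any staining
#' occurs (`texture_depth * g^0.15`) and that accumulating biofilm
#' progressively hides (`1 - opacity`). This is the structure that defeats
#' binary thresholding on real coupon photographs: a binary cut cannot
#' separate shaded clean substrate from genuinely fouled area. Gaussian
#' sensor noise is added last and the result clipped to 8 bits.
#'
#' @param params A [coupon_growth_params()].
#' @param size Image size in pixels, `c(height, width)` (default 500 x 500,
#'   ample for stable 256-bin histograms).
#' @return A deterministic (given `params$seed`) 3-channel [raster_image].
#' @examples
#' img <- generate_coupon_image(coupon_growth_params(0.5), size = c(64, 64))
#' @export
generate_coupon_image <- function(params, size = c(500L, 500L)) {
  stopifnot(inherits(params, "coupon_growth_params"))
  h <- as.integer(size[1L]); w <- as.integer(size[2L])
  stopifnot(h >= 1L, w >= 1L)
  with_seed(params$seed, {
    g <- params$growth_level
    f <- .blob_field(h, w, params$blob_count, params$blob_scale)
    tex <- .blob_field(h, w, 25L, 0.3)
    if (g <= 0) {
      opacity <- matrix(0, h, w)
      shade <- matrix(0, h, w)
    } else {
      # early-stage films are subtle and graded: peak opacity starts at
      # 0.45 and reaches full depth by growth 0.4
      depth <- min(1, 0.45 + 0.55 * g / 0.4)
      opacity <- depth * f^(params$stain_exponent / g)
      shade <- params$texture_depth * tex * g^0.15 * (1 - opacity)
    }
    px <- array(0, c(h, w, 3L))
    for (k in 1:3) {
      absorb <- 1 - params$stain_tint[k] / 255
      plane <- params$substrate_tint[k] * (1 - shade) *
        (1 - opacity * absorb)
      if (params$noise_sd > 0)
        plane <- plane + stats::rnorm(h * w, sd = params$noise_sd)
      px[, , k] <- pmin(pmax(round(plane), 0), 255)
    }
    raster_image(px, provenance = sprintf(
      "synthetic coupon (growth %.3f, seed %d)",
      params$growth_level, params$seed))
  })
}

#' Specification of a synthetic biofilm growth experiment
#'
#' Emulates the paired-coupon design: at each exposure time point,
#' replicate dishes each yield one coupon photographed after staining and
#' one sacrificed for the OD600 cell-density control. Suspended OD grows
#' exponentially in time with multiplicative lognormal replicate noise; the
#' photographed coupon's growth level is an affine map of log10 areal cell
#' density, saturating at 1.
#'
#' @param time_points_h Exposure times in hours, strictly increasing.
#' @param replicates Replicate coupons per time point (>= 1).
#' @param od600_start Suspension OD600 at the first time point (AU).
#' @param log10_od_increase Total log10 OD increase over the exposure
#'   (default 2 decades, keeping OD within the 0-1 AU assay range).
#' @param replicate_sdlog Lognormal sd of multiplicative replicate noise on
#'   OD.
#' @param suspension_volume,coupon_side,n_sides Control-assay geometry; see
#'   [od_measurement()].
#' @param density_log10_range log10 areal densities mapped to growth levels
#'   0 and 1.
#' @param image_size Pixel size of each generated coupon image; the default
#'   160 x 160 keeps a full series cheap while leaving histograms stable.
#' @param blob_count,blob_scale,noise_sd,substrate_tint,stain_tint,stain_exponent,texture_depth
#'   Per-image appearance; see [coupon_growth_params()].
#' @param seed Master RNG seed for the whole series.
#' @return An object of class `growth_series_spec`.
#' @export
growth_series_spec <- function(time_points_h = c(0, 48, 72, 144),
                               replicates = 3L,
                               od600_start = 0.006,
                               log10_od_increase = 2,
                               replicate_sdlog = 0.2,
                               suspension_volume = 15,
                               coupon_side = 2.5,
                               n_sides = 2L,
                               density_log10_range = c(6.2, 8.6),
                               image_size = c(160L, 160L),
                               blob_count = 40L,
                               blob_scale = 0.15,
                               noise_sd = 6,
                               substrate_tint = c(140, 165, 125),
                               stain_tint = c(95, 45, 110),
                               stain_exponent = 0.5,
                               texture_depth = 0.22,
                               seed = 1L) {
  if (length(time_points_h) < 2L || any(diff(time_points_h) <= 0))
    stop("`time_points_h` must be strictly increasing with >= 2 points",
         call. = FALSE)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  if (od600_start <= 0) stop("`od600_start` must be positive", call. = FALSE)
  if (diff(density_log10_range) <= 0)
    stop("`density_log10_range` must be increasing", call. = FALSE)
  structure(list(time_points_h = time_points_h,
                 replicates = as.integer(replicates),
                 od600_start = od600_start,
                 log10_od_increase = log10_od_increase,
                 replicate_sdlog = replicate_sdlog,
                 suspension_volume = suspension_volume,
                 coupon_side = coupon_side,
                 n_sides = as.integer(n_sides),
                 density_log10_range = density_log10_range,
                 image_size = as.integer(image_size),
                 blob_count = as.integer(blob_count),
                 blob_scale = blob_scale,
                 noise_sd = noise_sd,
                 substrate_tint = substrate_tint,
                 stain_tint = stain_tint,
                 stain_exponent = stain_exponent,
                 texture_depth = texture_depth,
                 seed = as.integer(seed)),
            class = "growth_series_spec")
}

#' Generate a full synthetic growth series with its control table
#'
#' @param spec A [growth_series_spec()].
#' @return A list with elements `images` (named list of [raster_image]s, one
#'   per sample), `manifest` (data frame: `sample_id`, `time_h`,
#'   `replicate`) and `control` (data frame: `sample_id`, `time_h`, `od600`,
#'   `cells_per_cm2`, `growth_level`). Deterministic given `spec$seed`.
#' @export
generate_growth_series <- function(spec) {
  stopifnot(inherits(spec, "growth_series_spec"))
  times <- rep(spec$time_points_h, each = spec$replicates)
  reps <- rep(seq_len(spec$replicates), times = length(spec$time_points_h))
  n <- length(times)
  sample_id <- sprintf("t%03d_r%d", as.integer(times), reps)

  rate <- spec$log10_od_increase / diff(range(spec$time_points_h))
  draws <- with_seed(spec$seed, list(
    noise = stats::rnorm(n, sd = spec$replicate_sdlog),
    image_seeds = sample.int(.Machine$integer.max, n)))

  od <- spec$od600_start * 10^(rate * (times - min(spec$time_points_h))) *
    exp(draws$noise)
  # the generative model's own conversion: no above-range assay warning
  dens <- suppressWarnings(vapply(od, function(o) areal_cell_density(
    od_measurement(o, spec$suspension_volume, spec$coupon_side,
                   spec$n_sides)), numeric(1L)))
  rng <- spec$density_log10_range
  growth <- pmin(pmax((log10(dens) - rng[1L]) / (rng[2L] - rng[1L]), 0), 1)

  images <- lapply(seq_len(n), function(i) {
    p <- coupon_growth_params(
      growth_level = growth[i],
      substrate_tint = spec$substrate_tint,
      stain_tint = spec$stain_tint,
      blob_count = spec$blob_count,
      blob_scale = spec$blob_scale,
      noise_sd = spec$noise_sd,
      stain_exponent = spec$stain_exponent,
      texture_depth = spec$texture_depth,
      seed = draws$image_seeds[i])
    generate_coupon_image(p, size = spec$image_size)
  })
  names(images) <- sample_id

  list(images = images,
       manifest = data.frame(sample_id = sample_id, time_h = times,
                             replicate = reps, stringsAsFactors = FALSE),
       control = data.frame(sample_id = sample_id, time_h = times,
                            od600 = od, cells_per_cm2 = dens,
                            growth_level = growth,
                            stringsAsFactors = FALSE))
}
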