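# Independent brute-force oracles and small fixture builders. These use
# direct definitional formulas (within-class variance, per-pixel class
# lookup), deliberately distinct from the package's cumulative-moment /
# dynamic-programming implementations.

gray_image <- function(values, nrow, ncol = length(values) / nrow) {
  raster_image(matrix(as.integer(values), nrow, ncol))
}

hist_from_values <- function(values) {
  channel_histogram(tabulate(as.integer(values) + 1L, nbins = 256L))
}

# A random histogram supported on `n_levels` distinct intensities.
random_sparse_histogram <- function(n_levels, max_count = 50L) {
  lv <- sort(sample(0:255, n_levels))
  counts <- integer(256)
  counts[lv + 1L] <- sample.int(max_count, n_levels, replace = TRUE)
  channel_histogram(counts)
}

# Count-weighted total within-class variance of a partition of the occupied
# levels into contiguous groups (boundaries = split positions after the
# i-th occupied level).
.within_var <- function(levels, counts, boundaries) {
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, length(levels))
  tot <- 0
  for (g in seq_along(starts)) {
    idx <- starts[g]:ends[g]
    w <- counts[idx]
    mu <- sum(w * levels[idx]) / sum(w)
    tot <- tot + sum(w * (levels[idx] - mu)^2)
  }
  tot
}

# Exhaustive-search multilevel Otsu over all C(d-1, N) partitions of the d
# occupied levels; ties resolved to the lexicographically smallest boundary
# vector (combn enumerates in that order and only strict improvements are
# kept). Returns integer thresholds: the top occupied level of each lower
# group, i.e. the smallest valid threshold for that partition.
brute_force_multilevel <- function(hist, n_thresholds) {
  occ <- which(hist$counts > 0L)
  levels <- occ - 1L
  counts <- hist$counts[occ]
  d <- length(levels)
  stopifnot(d > n_thresholds)
  combos <- utils::combn(d - 1L, n_thresholds)
  best <- Inf
  best_b <- NULL
  for (j in seq_len(ncol(combos))) {
    v <- .within_var(levels, counts, combos[, j])
    if (v < best - 1e-9) {
      best <- v
      best_b <- combos[, j]
    }
  }
  levels[best_b]
}

# Binary Otsu by direct definitional search over every candidate threshold.
brute_force_binary <- function(hist) {
  counts <- hist$counts
  lv <- 0:255
  best <- Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    lo <- counts[lv <= t]
    hi <- counts[lv > t]
    if (sum(lo) == 0L || sum(hi) == 0L) next
    vlo <- lv[lv <= t]
    vhi <- lv[lv > t]
    mlo <- sum(lo * vlo) / sum(lo)
    mhi <- sum(hi * vhi) / sum(hi)
    v <- sum(lo * (vlo - mlo)^2) + sum(hi * (vhi - mhi)^2)
    if (v < best - 1e-9) {
      best <- v
      best_t <- t
    }
  }
  best_t
}

# Per-pixel BGI oracle: look up every pixel's class by comparing against
# the thresholds one by one, apply the darkness weight, average.
bgi_pixel_oracle <- function(img, thresholds) {
  v <- as.vector(img$pixels)
  n <- length(thresholds$levels)
  cls <- vapply(v, function(x) sum(x > thresholds$levels), integer(1L))
  dark_weight <- (n - cls) / n  # class 0 (darkest) -> weight 1
  100 * mean(dark_weight)
}
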