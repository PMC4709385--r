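# End-to-end batch workflow over files: synth -> analyze/compare -> rank.

local_series_dir <- function(seed = 2, replicates = 2L,
                             env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  spec <- growth_series_spec(seed = seed, replicates = replicates,
                             image_size = c(48L, 48L))
  write_growth_series(spec, dir)
  dir
}

test_that("a written series round-trips through the batch analyzer", {
  dir <- local_series_dir()
  manifest <- file.path(dir, "manifest.csv")
  out <- analyze_batch(manifest, out_csv = file.path(dir, "bgi.csv"))
  expect_equal(nrow(out), 8L * 4L)  # 4 time points x 2 replicates x 4 channels
  expect_true(all(out$status == "ok"))
  expect_true(all(out$bgi >= 0 & out$bgi <= 100))
  expect_equal(sort(unique(out$channel)),
               sort(c("gray", "red", "green", "blue")))
  expect_true(all(out$a1 == 48L * 48L))
  expect_true(file.exists(file.path(dir, "bgi.csv")))
  cfg <- attr(out, "config")
  expect_equal(cfg$n_thresholds, 10L)
})

test_that("a missing image is flagged without stopping the batch", {
  dir <- local_series_dir(seed = 4)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  manifest$image[2] <- file.path(dir, "no-such-file.png")
  out <- analyze_batch(manifest, channels = "gray")
  bad <- out[out$sample_id == manifest$sample_id[2], ]
  expect_equal(nrow(bad), 1L)
  expect_match(bad$status, "not found")
  expect_true(all(out$status[out$sample_id != manifest$sample_id[2]] ==
                    "ok"))
})

test_that("per-row ROI columns override the default region", {
  dir <- local_series_dir(seed = 6, replicates = 1L)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)[1, , drop = FALSE]
  manifest$roi_row_start <- 0L
  manifest$roi_row_end <- 10L
  manifest$roi_col_start <- 0L
  manifest$roi_col_end <- 20L
  out <- analyze_batch(manifest, channels = "gray")
  expect_equal(out$a1, 200)
})

test_that("method comparison produces one row per image, method and channel", {
  dir <- local_series_dir(seed = 8)
  cmp <- compare_methods(file.path(dir, "manifest.csv"),
                         methods = c("bgi", "otsu", "manual"),
                         manual_range = c(0, 110),
                         channels = c("gray", "green"))
  expect_equal(nrow(cmp), 8L * 3L * 2L)
  expect_true(all(cmp$status == "ok"))
  expect_true(all(cmp$value >= 0 & cmp$value <= 100))
  expect_error(compare_methods(file.path(dir, "manifest.csv"),
                               methods = c("bgi", "manual")),
               "manual_range")
})

test_that("ranking joins metrics to the control and orders by fit", {
  dir <- local_series_dir(seed = 10, replicates = 3L)
  cmp <- compare_methods(file.path(dir, "manifest.csv"),
                         methods = c("bgi", "otsu"), channels = "gray")
  rk <- rank_from_tables(cmp, file.path(dir, "control.csv"),
                         out_csv = file.path(dir, "ranking.csv"))
  expect_equal(nrow(rk), 2L)
  expect_equal(rk$rank, 1:2)
  expect_true(all(diff(rk$score) <= 0))
  expect_setequal(rk$method, c("bgi/gray", "otsu/gray"))
  expect_true(file.exists(file.path(dir, "ranking.csv")))
  # unmatched sample ids are a join error naming the offender
  cmp$sample_id[1] <- "t999_r9"
  expect_error(rank_from_tables(cmp, file.path(dir, "control.csv")),
               "t999_r9")
})

test_that("a control table given as od600 is converted before ranking", {
  dens <- 10^seq(5, 8, length.out = 6)
  ctl <- data.frame(sample_id = paste0("s", 1:6),
                    od600 = dens * 12.5 / (3.9e8 * 15))
  metrics <- data.frame(sample_id = paste0("s", 1:6), method = "bgi",
                        channel = "gray",
                        value = log10(dens) * 10)
  rk <- rank_from_tables(rbind(metrics,
                               transform(metrics, method = "noise",
                                         value = c(3, 9, 1, 7, 2, 8))),
                         ctl)
  expect_equal(rk$method[1], "bgi/gray")
  expect_equal(rk$score[1], 1)
})

test_that("JSON reports embed scores and the resolved configuration", {
  img <- generate_coupon_image(coupon_growth_params(0.5, seed = 12),
                               size = c(40, 40))
  rep <- analyze_image(img, roi(5, 35, 5, 35))
  path <- withr::local_tempfile(fileext = ".json")
  write_bgi_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$a1, 900L)
  expect_named(back$channels, c("gray", "red", "green", "blue"))
  expect_equal(back$config$n_thresholds, 10L)
  expect_equal(back$config$roi$row_start, 5L)
  expect_equal(length(back$channels$gray$thresholds), 10L)
  expect_equal(back$channels$gray$bgi, rep$channels$gray$bgi)
})
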