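test_that("rolling_mean is a centered partial-window average", {
  x <- c(1, 2, 3, 4, 5)
  r <- rolling_mean(x, 3)
  expect_equal(r, c(mean(x[1:2]), 2, 3, 4, mean(x[4:5])))
  expect_equal(rolling_mean(x, 1), x)
  # a series shorter than the window is refused, not silently padded
  expect_error(rolling_mean(c(2, 4), 7), "shorter")
})

test_that("pool_series sums beds and trims the pre-harvest zeros", {
  ds <- one_flush_dataset(seed = 21)
  p <- pool_series(ds$yield)
  expect_true(all(c("day", "daily", "cumulative") %in% names(p)))
  y <- ds$yield
  tot <- tapply(y$stems, y$day, sum)
  expect_equal(p$daily, as.numeric(tot[as.character(p$day)]))
  expect_equal(p$cumulative, cumsum(p$daily))
  expect_equal(min(p$day), attr(p, "first_harvest_day"))
})

test_that("find_boundaries locates rate minima and merges near-duplicates", {
  # synthetic rate: three humps with pronounced troughs at 40 and 80
  day <- 0:120
  rate <- dnorm(day, 20, 8) + dnorm(day, 60, 8) + dnorm(day, 100, 8)
  rt <- data.frame(day = day, rate = rate)
  cfg <- segmentation_config()
  b <- find_boundaries(rt, cfg)
  expect_equal(b, c(40, 80))
  # two candidate minima 10 days apart collapse to the deeper one
  rate2 <- dnorm(day, 20, 8) + dnorm(day, 60, 8) -
    0.001 * (day == 35) - 0.003 * (day == 45)
  b2 <- find_boundaries(data.frame(day = day, rate = rate2), cfg)
  expect_equal(length(b2), 1)
})

test_that("segment_flushes recovers noiseless boundaries", {
  starts <- c(91, 160, 230)
  tr <- clean_truths(starts)
  ds <- simulate_experiment(design = experiment_design(horizon = 300),
                            flushes = tr, seed = 31)
  cfg <- segmentation_config(method = "loess", loess_span = 0.1)
  b <- segment_flushes(ds$yield, cfg)
  expect_s3_class(b, "flush_boundaries")
  d <- b$boundary_days
  expect_equal(length(d), length(starts))
  # first flush opens at the first pooled harvest day
  expect_equal(d[1], min(pool_series(ds$yield)$day))
  expect_true(all(abs(d - starts) <= 3))
})

test_that("boundary_rmse is the RMS day shift", {
  d <- c(91, 129, 186, 240)
  expect_identical(boundary_rmse(d, d), 0)
  expect_identical(boundary_rmse(d + 2, d), 2)
  expect_equal(boundary_rmse(d + c(3, -4, 0, 0), d), sqrt(25 / 4))
  expect_error(boundary_rmse(d, d[-1]), "length")
})

test_that("sensitivity_analysis flags non-comparable settings and scores the rest", {
  starts <- c(91, 160, 230)
  ds <- simulate_experiment(design = experiment_design(horizon = 300),
                            flushes = clean_truths(starts), seed = 32)
  pooled <- pool_series(ds$yield)
  ref <- segmentation_config(method = "loess", loess_span = 0.1)
  rep <- suppressWarnings(
    sensitivity_analysis(pooled, gam_dims = c(12, 18),
                         spans = c(0.05, 0.1, 0.2), reference = ref))
  g <- rep$grid
  # the reference setting itself appears in the grid with RMSE zero
  self <- which(g$method == "loess" & g$parameter == 0.1)
  expect_true(g$comparable[self])
  expect_identical(g$rmse[self], 0)
  expect_true(all(is.na(g$rmse[!g$comparable])))
  expect_true(rep$recommended %in% which(g$comparable))
})

test_that("split_flushes partitions the series and transforms coordinates", {
  ds <- one_flush_dataset(seed = 41)
  y <- validate_yield_series(ds$yield)
  b <- flush_boundaries(y, c(0, 30))
  fl <- split_flushes(y, b)
  # exact partition: every (bed, day) at or after the first boundary
  # appears exactly once, in the right flush
  expect_equal(nrow(fl), nrow(y))
  expect_true(all(fl$flush[fl$day < 30] == 1))
  expect_true(all(fl$flush[fl$day >= 30] == 2))
  key_in <- paste(y$bed_id, y$day)
  key_out <- paste(fl$bed_id, fl$day)
  expect_setequal(key_out, key_in)
  expect_false(any(duplicated(key_out)))
  # coordinate transform round-trip: yprime + offset == cumulative
  off <- b$offsets[cbind(fl$bed_id, paste0("flush", fl$flush))]
  expect_equal(fl$yprime + off, fl$cumulative)
  expect_equal(fl$tprime, fl$day - c(0, 30)[fl$flush])
  # per-bed stems within each flush still sum to the yprime endpoint
  one <- fl[fl$bed_id == fl$bed_id[1] & fl$flush == 2, ]
  expect_equal(sum(one$stems), one$yprime[which.max(one$tprime)])
})

test_that("build_weights down-weights pause and catch-up days only", {
  ds <- one_flush_dataset(seed = 42)
  fl <- split_flushes(validate_yield_series(ds$yield),
                      flush_boundaries(ds$yield, 0))
  p <- pause_spec(pause_start = 20, pause_end = 26, catchup_end = 30)
  w <- build_weights(fl, p)
  expect_equal(unique(w[fl$day >= 20 & fl$day <= 30]), 0.01)
  expect_equal(unique(w[fl$day < 20 | fl$day > 30]), 1)
  expect_equal(build_weights(fl, NULL), rep(1, nrow(fl)))
})
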