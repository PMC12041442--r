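test_that("experiment_design lays out blocks x treatments", {
  d <- experiment_design()
  expect_s3_class(d, "experiment_design")
  expect_equal(nrow(d$beds), 15)
  expect_equal(sort(unique(d$beds$treatment)),
               sort(c("R", "T", "C", "R50", "Control")))
  expect_equal(as.vector(table(d$beds$block_id)), rep(5L, 3))
  # every treatment appears once per block
  tab <- table(d$beds$block_id, d$beds$treatment)
  expect_true(all(tab == 1))
})

test_that("simulate_experiment is reproducible and seed-sensitive", {
  a <- one_flush_dataset(seed = 11)
  b <- one_flush_dataset(seed = 11)
  c <- one_flush_dataset(seed = 12)
  expect_identical(a$yield, b$yield)
  expect_false(identical(a$yield$stems, c$yield$stems))
})

test_that("daily counts are non-negative integers that sum to the rounded curve", {
  ds <- one_flush_dataset(seed = 3)
  y <- ds$yield
  expect_true(all(y$stems >= 0))
  expect_true(all(y$stems == round(y$stems)))
  # carry-forward rounding: each bed's total equals its noisy cumulative
  # total rounded once, not the sum of per-day roundings
  eff <- ds$truth$effects[[1]]
  ndays <- length(unique(y$day))
  for (b in unique(y$bed_id)) {
    tot <- sum(y$stems[y$bed_id == b])
    A_i <- eff$A_i[eff$bed_id == b]
    # total is within accumulated noise (sd 5 per day) of the realised
    # asymptote, allowing ~2% for the unsaturated curve tail
    expect_lt(abs(tot - A_i), 4 * 5 * sqrt(ndays) + 0.02 * A_i)
  }
})

test_that("cumulative column is the running sum per bed", {
  ds <- one_flush_dataset(seed = 5)
  y <- validate_yield_series(ds$yield)
  for (b in unique(y$bed_id)[1:3]) {
    sub <- y[y$bed_id == b, ]
    sub <- sub[order(sub$day), ]
    expect_equal(sub$cumulative, cumsum(sub$stems))
  }
})

test_that("non-positive drawn asymptotes are redrawn with a warning", {
  tr <- one_flush_truth(A = c(R = 10, T = 10, C = 10, R50 = 10, Control = 10),
                        sigma_bed_A = 200)
  suppressWarnings(expect_warning(
    ds <- simulate_experiment(design = experiment_design(horizon = 70),
                              flushes = list(tr), seed = 2),
    "redraw"))
  expect_true(all(ds$truth$effects[[1]]$A_i > 0))
})

test_that("pause injection moves harvest but conserves every bed total", {
  tr <- list(flush_truth(1, 0, A = five_A, B = five_B, C = 0.1),
             flush_truth(2, 60, A = five_A, B = five_B, C = 0.1))
  des <- experiment_design(horizon = 130)
  base <- simulate_experiment(design = des, flushes = tr, seed = 9)
  p <- pause_spec(pause_start = 20, pause_end = 30, catchup_end = 36)
  paused <- simulate_experiment(design = des, flushes = tr, pause = p, seed = 9)
  expect_true(all(paused$yield$stems[paused$yield$day >= 20 &
                                       paused$yield$day <= 30] == 0))
  tot0 <- tapply(base$yield$stems, base$yield$bed_id, sum)
  tot1 <- tapply(paused$yield$stems, paused$yield$bed_id, sum)
  expect_equal(tot1, tot0)
  # outside pause + catch-up the series is untouched
  out <- base$yield$day < 20 | base$yield$day > 36
  expect_equal(paused$yield$stems[out], base$yield$stems[out])
})

test_that("yield csv round-trips exactly", {
  ds <- one_flush_dataset(seed = 7)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_yield_csv(ds$yield, path)
  back <- read_yield_csv(path)
  cols <- c("bed_id", "block_id", "treatment", "day", "stems")
  expect_equal(back[, cols], validate_yield_series(ds$yield)[, cols])
})

test_that("validate_yield_series rejects malformed tables", {
  ds <- one_flush_dataset(seed = 8)
  y <- ds$yield
  expect_error(validate_yield_series(y[, setdiff(names(y), "stems")]),
               "stems")
  bad <- y; bad$stems[4] <- -2
  expect_error(validate_yield_series(bad), "negative")
  bad <- y; bad$stems[4] <- 1.5
  expect_error(validate_yield_series(bad), "integer")
  bad <- rbind(y, y[1, ])
  expect_error(validate_yield_series(bad), "duplicate")
  bad <- y[!(y$bed_id == y$bed_id[1] & y$day == 10), ]
  expect_error(validate_yield_series(bad), "gap")
})

test_that("flush_truth validates its arguments", {
  expect_error(flush_truth(1, 0, A = -5, B = 2))
  expect_error(flush_truth(1, 0, A = 100, B = 2, C = -0.1))
  expect_error(flush_truth(1, 0, A = 100, B = 2, noise_sd = -1))
})

test_that("treatment-named parameters map onto beds; scalars recycle", {
  ds <- one_flush_dataset(seed = 13, sigma_block_A = 0, sigma_bed_A = 0,
                          sigma_bed_B = 0)
  eff <- ds$truth$effects[[1]]
  expect_equal(eff$A_i, unname(five_A[eff$treatment]))
  tr <- one_flush_truth(A = 900, B = 2)
  ds2 <- simulate_experiment(design = experiment_design(horizon = 70),
                             flushes = list(tr), seed = 13)
  expect_equal(unique(ds2$truth$effects[[1]]$A_i -
                        ds2$truth$effects[[1]]$bed_A -
                        ds2$truth$effects[[1]]$block_A), 900)
})
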