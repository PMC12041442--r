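test_that("nlme_spec validates and carries defaults", {
  sp <- nlme_spec()
  expect_s3_class(sp, "nlme_spec")
  expect_equal(sp$start, c(A = 1000, B = 2, C = 0.1))
  expect_equal(sp$estimator, "saem")
  expect_error(nlme_spec(n_burnin = -1))
  expect_error(nlme_spec(start = c(A = -10, B = 2, C = 0.1)))
})

test_that("fit_flush validates its inputs", {
  fl <- one_flush_data(seed = 51)
  expect_error(fit_flush(fl[, setdiff(names(fl), "yprime")], spec = fast_spec()),
               "yprime")
  expect_error(fit_flush(fl, weights = rep(1, 3), spec = fast_spec()),
               "weight")
  expect_error(fit_flush(fl, weights = rep(-1, nrow(fl)), spec = fast_spec()),
               "weight")
})

test_that("the stochastic EM fit recovers a clean single flush", {
  fl <- one_flush_data(seed = 52)
  fit <- fit_flush(fl, spec = fast_spec(seed = 52))
  expect_s3_class(fit, "gompertz_fit")
  est <- fit$estimates
  a <- est[est$parameter == "A", ]
  expect_setequal(a$treatment, names(five_A))
  for (tr in names(five_A))
    expect_lt(abs(a$estimate[a$treatment == tr] - five_A[[tr]]) / five_A[[tr]],
              0.2)
  expect_lt(abs(est$estimate[est$parameter == "C"] - 0.1), 0.02)
  expect_true(all(est$se[!is.na(est$se)] > 0))
  expect_gt(fit$r2, 0.98)
  # fitted values align with the data rows
  expect_equal(nrow(fit$fitted), nrow(fl))
})

test_that("the fit is reproducible under the spec seed", {
  fl <- one_flush_data(seed = 53)
  f1 <- fit_flush(fl, spec = fast_spec(seed = 7))
  f2 <- fit_flush(fl, spec = fast_spec(seed = 7))
  expect_identical(f1$estimates, f2$estimates)
})

test_that("all-ones weights reproduce the unweighted fit exactly", {
  fl <- one_flush_data(seed = 54)
  f0 <- fit_flush(fl, spec = fast_spec(seed = 3))
  f1 <- fit_flush(fl, weights = rep(1, nrow(fl)), spec = fast_spec(seed = 3))
  expect_identical(f0$estimates, f1$estimates)
  expect_identical(f0$vcov, f1$vcov)
})

test_that("down-weighting a corrupted stretch changes and improves the fit", {
  tr <- one_flush_truth()
  des <- experiment_design(horizon = 70)
  ds <- simulate_experiment(design = des, flushes = list(tr),
                            pause = pause_spec(20, 26, 30), seed = 55)
  fl <- split_flushes(validate_yield_series(ds$yield),
                      flush_boundaries(ds$yield, 0))
  w <- build_weights(fl, pause_spec(20, 26, 30))
  f_plain <- fit_flush(fl, spec = fast_spec(seed = 4))
  f_wt <- fit_flush(fl, weights = w, spec = fast_spec(seed = 4))
  expect_false(identical(f_plain$estimates$estimate, f_wt$estimates$estimate))
  expect_true(f_wt$weighted)
  # residuals on the clean days should not be worse under down-weighting
  # (flush starts at day 0, so tprime == day here)
  clean <- f_plain$fitted$tprime < 20 | f_plain$fitted$tprime > 30
  rss_plain <- sum((f_plain$fitted$yprime - f_plain$fitted$fitted)[clean]^2)
  rss_wt <- sum((f_wt$fitted$yprime - f_wt$fitted$fitted)[clean]^2)
  expect_lt(rss_wt, rss_plain * 1.05)
})

test_that("non-stabilised runs raise a typed convergence error with a trace", {
  fl <- one_flush_data(seed = 56)
  err <- tryCatch(
    fit_flush(fl, spec = fast_spec(seed = 5, n_burnin = 5, n_smooth = 10,
                                   convergence_window = 10,
                                   convergence_tol = 1e-10)),
    error = function(e) e)
  expect_s3_class(err, "flushcurve_convergence_error")
  expect_true(is.matrix(err$trace))
})

test_that("two-stage estimator agrees with the stochastic EM on clean data", {
  fl <- one_flush_data(seed = 57)
  f1 <- fit_flush(fl, spec = fast_spec(seed = 6))
  f2 <- fit_flush(fl, spec = fast_spec(estimator = "two_stage"))
  expect_equal(f2$estimator, "two_stage")
  a1 <- f1$estimates[f1$estimates$parameter == "A", ]
  a2 <- f2$estimates[f2$estimates$parameter == "A", ]
  m <- merge(a1, a2, by = "treatment")
  expect_lt(max(abs(m$estimate.x - m$estimate.y) / m$estimate.y), 0.1)
})

test_that("sparse flushes fit with a warning rather than failing", {
  fl <- one_flush_data(seed = 58)
  thin <- fl[fl$tprime %in% seq(0, 68, by = 20), ]
  expect_warning(fit_flush(thin, spec = fast_spec(seed = 8)),
                 "observation")
})

test_that("a half-size experiment and a single flush with 3 treatments also fit", {
  des <- experiment_design(n_blocks = 2, treatments = c("X", "Y", "Z"),
                           horizon = 60)
  tr <- flush_truth(1, 0, A = c(X = 900, Y = 1100, Z = 1000),
                    B = 2.2, C = 0.11)
  ds <- simulate_experiment(design = des, flushes = list(tr), seed = 59)
  fl <- split_flushes(validate_yield_series(ds$yield),
                      flush_boundaries(ds$yield, 0))
  fit <- fit_flush(fl, spec = fast_spec(seed = 9))
  expect_setequal(fit$estimates$treatment[fit$estimates$parameter == "A"],
                  c("X", "Y", "Z"))
})
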