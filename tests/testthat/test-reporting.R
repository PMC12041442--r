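test_that("treatment_table collects per-flush estimates in long form", {
  fl <- one_flush_data(seed = 71)
  fit <- fit_flush(fl, spec = fast_spec(seed = 13))
  tab <- treatment_table(list(fit))
  expect_equal(sort(unique(tab$parameter)), c("A", "B", "C"))
  expect_equal(unique(tab$flush), 1)
  expect_equal(sum(tab$parameter == "A"), 5)
  expect_true(all(is.na(tab$treatment[tab$parameter == "C"])))
  # flush attribute wins over list position
  attr(fit, "flush") <- 4
  expect_equal(unique(treatment_table(list(fit))$flush), 4)
})

test_that("contrast_vs_control computes Wald intervals with covariance", {
  fl <- one_flush_data(seed = 72)
  fit <- fit_flush(fl, spec = fast_spec(seed = 14))
  cc <- contrast_vs_control(list(fit), "Control")
  expect_setequal(unique(cc$treatment), setdiff(names(five_A), "Control"))
  expect_true(all(cc$covariance_used))
  r <- cc[cc$treatment == "R" & cc$parameter == "A", ]
  est <- fit$estimates
  d <- est$estimate[est$parameter == "A" & est$treatment == "R"] -
    est$estimate[est$parameter == "A" & est$treatment == "Control"]
  expect_equal(r$difference, d)
  V <- fit$vcov
  expect_equal(r$se, sqrt(V["A_R", "A_R"] + V["A_Control", "A_Control"] -
                            2 * V["A_R", "A_Control"]))
  expect_equal(r$lower, r$difference - qnorm(0.975) * r$se)
  expect_equal(r$significant, r$lower > 0 || r$upper < 0)
  # data-frame input falls back to zero covariance and flags it
  cc2 <- contrast_vs_control(treatment_table(list(fit)), "Control")
  expect_false(any(cc2$covariance_used))
  expect_error(contrast_vs_control(list(fit), "NoSuchTreatment"), "control")
})

test_that("run_pipeline ties the stages together on a small experiment", {
  trs <- list(flush_truth(1, 0, A = five_A, B = five_B, C = 0.12),
              flush_truth(2, 60, A = five_A + 200, B = five_B, C = 0.12))
  cfg <- pipeline_config(
    design = experiment_design(horizon = 125),
    flushes = trs,
    segmentation = segmentation_config(method = "loess", loess_span = 0.15),
    seed = 73)
  rep <- run_pipeline(cfg)
  expect_s3_class(rep, "run_report")
  expect_equal(rep$provenance$n_flushes_detected, 2)
  expect_equal(length(rep$gompertz_fits), 2)
  expect_equal(length(rep$gamm_fits), 2)
  expect_equal(nrow(rep$failures), 0)
  expect_equal(sort(unique(rep$treatment_table$flush)), c(1, 2))
  expect_true(all(c("r2_gamm", "r2_gompertz") %in% names(rep$comparisons)))
  tt <- trajectory_table(rep)
  expect_true(all(c("flush", "treatment", "parameter", "estimate") %in% names(tt)))
})

test_that("pipeline isolates per-flush failures instead of aborting", {
  trs <- list(flush_truth(1, 0, A = five_A, B = five_B, C = 0.12),
              flush_truth(2, 60, A = five_A + 200, B = five_B, C = 0.12))
  cfg <- pipeline_config(
    design = experiment_design(horizon = 125),
    flushes = trs,
    segmentation = segmentation_config(method = "loess", loess_span = 0.15),
    nlme = nlme_spec(start_values = "data", n_burnin = 5, n_smooth = 10,
                     convergence_window = 10, convergence_tol = 1e-12),
    seed = 73)
  rep <- run_pipeline(cfg)
  expect_gt(nrow(rep$failures), 0)
  expect_true(all(rep$failures$stage == "gompertz"))
  # the flexible benchmark still fitted every flush
  expect_equal(length(rep$gamm_fits), 2)
})

test_that("write_report produces the text outputs", {
  trs <- list(flush_truth(1, 0, A = five_A, B = five_B, C = 0.12))
  cfg <- pipeline_config(
    design = experiment_design(horizon = 65),
    flushes = trs,
    segmentation = segmentation_config(method = "loess", loess_span = 0.15),
    seed = 74, output_dir = tempfile("report"))
  rep <- suppressWarnings(run_pipeline(cfg))
  on.exit(unlink(cfg$output_dir, recursive = TRUE))
  files <- list.files(cfg$output_dir)
  expect_true(all(c("boundaries.csv", "treatment_table.csv", "contrasts.csv",
                    "model_comparison.csv", "diagnostics.json") %in% files))
  dg <- jsonlite::read_json(file.path(cfg$output_dir, "diagnostics.json"))
  expect_equal(dg$seed, 74)
  tab <- utils::read.csv(file.path(cfg$output_dir, "treatment_table.csv"))
  expect_equal(nrow(tab), nrow(rep$treatment_table))
})

test_that("plot_outputs writes figures without failing the run", {
  trs <- list(flush_truth(1, 0, A = five_A, B = five_B, C = 0.12))
  cfg <- pipeline_config(
    design = experiment_design(horizon = 65),
    flushes = trs,
    segmentation = segmentation_config(method = "loess", loess_span = 0.15),
    seed = 75)
  rep <- suppressWarnings(run_pipeline(cfg))
  dir <- tempfile("figs")
  plot_outputs(rep, dir)
  on.exit(unlink(dir, recursive = TRUE))
  expect_gt(length(list.files(dir, pattern = "[.]png$")), 0)
})

test_that("reading back a written dataset reproduces the in-memory pipeline", {
  trs <- list(flush_truth(1, 0, A = five_A, B = five_B, C = 0.12))
  ds <- simulate_experiment(design = experiment_design(horizon = 65),
                            flushes = trs, seed = 76)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_yield_csv(ds, path)
  cfg <- pipeline_config(
    input = path,
    segmentation = segmentation_config(method = "loess", loess_span = 0.15),
    seed = 76)
  rep <- suppressWarnings(run_pipeline(cfg))
  # the saturated tail of a lone flush can produce a spurious late
  # boundary; the read-back path must still segment and fit
  expect_gte(rep$provenance$n_flushes_detected, 1)
  expect_gte(length(rep$gompertz_fits), 1)
  expect_null(rep$truth)
})
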