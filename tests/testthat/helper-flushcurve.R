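# Shared fixtures for the test suite. Small single-flush designs keep the
# unit tests fast; the acceptance tests build their own full-size data.

five_A <- c(R = 1400, T = 1300, C = 1200, R50 = 1250, Control = 1000)
five_B <- c(R = 2.3, T = 2.3, C = 2.3, R50 = 2.3, Control = 2.2)

one_flush_truth <- function(...) {
  args <- utils::modifyList(
    list(k = 1, start_day = 0, A = five_A, B = five_B, C = 0.1), list(...))
  do.call(flush_truth, args)
}

one_flush_dataset <- function(seed = 1, horizon = 70, ...) {
  simulate_experiment(design = experiment_design(horizon = horizon),
                      flushes = list(one_flush_truth(...)), seed = seed)
}

one_flush_data <- function(seed = 1, horizon = 70, ...) {
  ds <- one_flush_dataset(seed = seed, horizon = horizon, ...)
  split_flushes(ds$yield, flush_boundaries(ds$yield, 0))
}

fast_spec <- function(seed = 99, ...) {
  args <- utils::modifyList(list(start_values = "data", seed = seed), list(...))
  do.call(nlme_spec, args)
}

# two-flush truths with noiseless counts and no random effects, for
# segmentation tests that need exactly recoverable boundaries
clean_truths <- function(start_days, A = 1200, B = 2.3, C = 0.12,
                         design = experiment_design(horizon = max(start_days) + 70)) {
  lapply(seq_along(start_days), function(k)
    flush_truth(k, start_days[k], A = A, B = B, C = C,
                sigma_block_A = 0, sigma_bed_A = 0, sigma_bed_B = 0,
                noise_sd = 0))
}
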