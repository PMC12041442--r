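#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings. Exactly one data source is used: a CSV
#' of daily yield records (`input`), or a synthetic experiment defined by
#' `design` + `flushes` (the default).
#'
#' @param input Optional path to a yield CSV (see [read_yield_csv()]).
#' @param design,flushes Synthetic-data design and ground truth, used when
#'   `input` is `NULL`.
#' @param segmentation A [segmentation_config()].
#' @param nlme An [nlme_spec()]. The pipeline default uses the data-driven
#'   initializer, since flush scales vary widely across a maturing crop.
#' @param gamm A [gamm_config()].
#' @param pause Optional [pause_spec()] — injected into synthetic data and
#'   always used to down-weight the affected days during fitting.
#' @param control Control treatment label for contrasts.
#' @param output_dir Optional directory for CSV/JSON artifacts and plots.
#' @param seed Global seed: drives the synthetic data and the per-flush
#'   SAEM fits.
#' @param verbose Emit progress messages?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            design = experiment_design(),
                            flushes = default_flush_truths(design),
                            segmentation = segmentation_config(),
                            nlme = nlme_spec(start_values = "data"),
                            gamm = gamm_config(),
                            pause = NULL,
                            control = "Control",
                            output_dir = NULL,
                            seed = 1,
                            verbose = FALSE) {
  if (!is.null(input) && !is.null(design) && !missing(design))
    stop("give either an input CSV or a synthetic design, not both")
  if (is.null(input)) {
    stopifnot(inherits(design, "experiment_design"))
    if (!control %in% design$treatments)
      stop("control label '", control, "' is not among the treatments")
  }
  structure(list(input = input, design = design, flushes = flushes,
                 segmentation = segmentation, nlme = nlme, gamm = gamm,
                 pause = pause, control = control, output_dir = output_dir,
                 seed = seed, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full repeated-growth-curve analysis
#'
#' Pool, segment, split, weight, fit (Gompertz mixed model and additive
#' mixed model per flush), and assemble parameter, contrast and
#' model-comparison tables. Any per-flush fit failure is logged and the
#' run continues with the remaining flushes. Deterministic given the
#' config's seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: list with `data`, `truth`
#'   (synthetic runs only), `boundaries`, `flush_data`, `gompertz_fits`,
#'   `gamm_fits`, `treatment_table`, `contrasts`, `comparisons`,
#'   `failures` and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)

  if (!is.null(config$input)) {
    say("reading ", config$input)
    data <- read_yield_csv(config$input)
    truth <- NULL
  } else {
    say("simulating ", length(config$flushes), "-flush experiment (seed ",
        config$seed, ")")
    ds <- simulate_experiment(config$design, config$flushes,
                              pause = config$pause, seed = config$seed)
    data <- ds$yield
    truth <- ds$truth
  }

  say("segmenting flushes")
  boundaries <- segment_flushes(data, config$segmentation)
  flush_data <- split_flushes(data, boundaries)
  flush_ids <- sort(unique(flush_data$flush))

  fit_seeds <- derive_seeds(config$seed, length(flush_ids))
  gomp <- list(); gamm <- list(); failures <- list()
  for (k in flush_ids) {
    sub <- flush_data[flush_data$flush == k, ]
    w <- build_weights(sub, config$pause)
    spec_k <- config$nlme
    spec_k$seed <- fit_seeds[match(k, flush_ids)]
    g <- tryCatch(fit_flush(sub, w, spec_k), error = function(e) e)
    if (inherits(g, "error")) {
      failures[[length(failures) + 1]] <- data.frame(
        stage = "gompertz", flush = k, message = conditionMessage(g))
      say("flush ", k, ": Gompertz fit failed: ", conditionMessage(g))
    } else {
      attr(g, "flush") <- k
      gomp[[as.character(k)]] <- g
    }
    a <- tryCatch(fit_gamm_flush(sub, config$gamm, w), error = function(e) e)
    if (inherits(a, "error")) {
      failures[[length(failures) + 1]] <- data.frame(
        stage = "gamm", flush = k, message = conditionMessage(a))
      say("flush ", k, ": additive fit failed: ", conditionMessage(a))
    } else {
      attr(a, "flush") <- k
      gamm[[as.character(k)]] <- a
    }
    say("flush ", k, " done")
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(stage = character(), flush = integer(), message = character())

  ttab <- if (length(gomp)) treatment_table(restore_flush_ids(gomp)) else NULL
  contrasts <- if (length(gomp))
    tryCatch(contrast_vs_control(restore_flush_ids(gomp), config$control),
             error = function(e) NULL) else NULL
  comparisons <- NULL
  both <- intersect(names(gomp), names(gamm))
  if (length(both)) {
    comparisons <- do.call(rbind, lapply(both, function(k) {
      s <- compare_fits(gamm[[k]], gomp[[k]])$summary
      data.frame(flush = as.integer(k), r2_gamm = s$r2_gamm,
                 r2_gompertz = s$r2_gompertz, delta_r2 = s$delta_r2,
                 max_abs_deviation = s$max_abs_deviation,
                 at_tprime = s$at_tprime)
    }))
  }

  report <- structure(list(
    data = data, truth = truth, boundaries = boundaries,
    flush_data = flush_data, gompertz_fits = gomp, gamm_fits = gamm,
    treatment_table = ttab, contrasts = contrasts, comparisons = comparisons,
    failures = failures,
    provenance = list(seed = config$seed, config = config,
                      package_version = as.character(utils::packageVersion("flushcurve")),
                      n_flushes_detected = length(flush_ids),
                      n_fitted = length(gomp))
  ), class = "run_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# re-attach flush indices (list names) as attributes for treatment_table
restore_flush_ids <- function(fits) {
  lapply(names(fits), function(k) {
    f <- fits[[k]]
    attr(f, "flush") <- as.integer(k)
    f
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("Repeated growth-curve run report\n")
  cat("  flushes detected:", length(x$boundaries$boundary_days),
      " Gompertz fits:", length(x$gompertz_fits),
      " additive fits:", length(x$gamm_fits),
      " failures:", nrow(x$failures), "\n")
  if (!is.null(x$comparisons)) {
    cat("  Efron R^2 (Gompertz):",
        paste(round(x$comparisons$r2_gompertz, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parameter trajectories across flushes
#'
#' Extracts the per-treatment `A` and `B` estimates against flush index —
#' the maturation view of the crop — plus qualitative flags: does the
#' asymptote rise over the early flushes (1 to 4) and does the growth-rate
#' parameter decline from the first multi-flush estimate to the last, for
#' every treatment? Missing flushes are flagged.
#'
#' @param report A `run_report`, or a [treatment_table()] data frame.
#' @return Data frame `flush`, `treatment`, `parameter`, `estimate`, `se`
#'   with attributes `A_increasing_early`, `B_declining` and
#'   `missing_flushes`.
#' @export
trajectory_table <- function(report) {
  tab <- if (inherits(report, "run_report")) report$treatment_table else report
  if (is.null(tab) || !nrow(tab)) stop("no fitted flushes to tabulate")
  tab <- tab[tab$parameter %in% c("A", "B"), ]
  flushes <- sort(unique(tab$flush))
  gaps <- setdiff(seq(min(flushes), max(flushes)), flushes)
  early <- flushes[flushes <= 4]
  flags <- list(A_increasing_early = NA, B_declining = NA,
                missing_flushes = gaps)
  if (length(early) >= 2) {
    a <- tab[tab$parameter == "A" & tab$flush %in% range(early), ]
    flags$A_increasing_early <- all(vapply(unique(a$treatment), function(tt) {
      s <- a[a$treatment == tt, ]
      s$estimate[s$flush == max(early)] > s$estimate[s$flush == min(early)]
    }, logical(1)))
  }
  if (length(flushes) >= 2) {
    b <- tab[tab$parameter == "B" & tab$flush %in% range(flushes), ]
    flags$B_declining <- all(vapply(unique(b$treatment), function(tt) {
      s <- b[b$treatment == tt, ]
      s$estimate[s$flush == max(flushes)] < s$estimate[s$flush == min(flushes)]
    }, logical(1)))
  }
  out <- tab[order(tab$parameter, tab$treatment, tab$flush),
             c("flush", "treatment", "parameter", "estimate", "se")]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out), flags)
  out
}

# Write the report's tables and provenance into a directory.
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(flush = seq_along(report$boundaries$boundary_days),
                              start_day = report$boundaries$boundary_days),
                   file.path(dir, "boundaries.csv"), row.names = FALSE)
  if (!is.null(report$treatment_table))
    utils::write.csv(report$treatment_table,
                     file.path(dir, "treatment_table.csv"), row.names = FALSE)
  if (!is.null(report$contrasts))
    utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                     row.names = FALSE)
  if (!is.null(report$comparisons))
    utils::write.csv(report$comparisons, file.path(dir, "model_comparison.csv"),
                     row.names = FALSE)
  if (nrow(report$failures))
    utils::write.csv(report$failures, file.path(dir, "failures.csv"),
                     row.names = FALSE)
  prov <- report$provenance
  diag <- list(seed = prov$seed, package_version = prov$package_version,
               n_flushes_detected = prov$n_flushes_detected,
               n_fitted = prov$n_fitted,
               estimators = vapply(report$gompertz_fits, `[[`, "", "estimator"),
               acceptance_rates = vapply(report$gompertz_fits, `[[`,
                                         numeric(1), "acceptance_rate"),
               r2_gompertz = vapply(report$gompertz_fits, `[[`,
                                    numeric(1), "r2"),
               r2_gamm = vapply(report$gamm_fits, `[[`, numeric(1), "r2"))
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write diagnostic figures for a run report
#'
#' Per-flush fit overlays (observed flush-local cumulative yield with the
#' population-level Gompertz curves per treatment), the A and B parameter
#' trajectories, and the contrast panels with confidence-interval bars.
#' Purely a convenience: any plotting failure degrades to a warning.
#'
#' @param report A `run_report`.
#' @param dir Output directory for PNG files (deterministic names keyed by
#'   flush index).
#' @return Character vector of files written, invisibly.
#' @export
plot_outputs <- function(report, dir) {
  files <- character(0)
  res <- tryCatch({
    if (!length(report$gompertz_fits)) {
      warning("empty report; no figures written")
      return(invisible(files))
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (k in names(report$gompertz_fits)) {
      f <- report$gompertz_fits[[k]]
      path <- file.path(dir, sprintf("flush%02d_fit.png", as.integer(k)))
      grDevices::png(path, width = 900, height = 600)
      d <- f$fitted
      trts <- sort(unique(d$treatment))
      cols <- stats::setNames(grDevices::hcl.colors(length(trts), "Dark 2"), trts)
      plot(d$tprime, d$yprime, col = cols[d$treatment], pch = 16, cex = 0.5,
           xlab = "days since flush start", ylab = "cumulative stems (flush-local)",
           main = sprintf("Flush %s: Gompertz fit (R^2 = %.3f)", k, f$r2))
      for (tt in trts) {
        s <- d[d$treatment == tt, ]
        s <- s[order(s$tprime), ]
        lines(s$tprime, s$fitted_population, col = cols[tt], lwd = 2)
      }
      legend("bottomright", legend = trts, col = cols, lwd = 2, bty = "n")
      grDevices::dev.off()
      files <- c(files, path)
    }
    tab <- report$treatment_table
    for (par in c("A", "B")) {
      path <- file.path(dir, sprintf("trajectory_%s.png", par))
      grDevices::png(path, width = 900, height = 600)
      s <- tab[tab$parameter == par, ]
      trts <- sort(unique(s$treatment))
      cols <- stats::setNames(grDevices::hcl.colors(length(trts), "Dark 2"), trts)
      plot(range(s$flush), range(s$estimate), type = "n",
           xlab = "flush", ylab = paste("parameter", par),
           main = paste("Across-flush trajectory of", par))
      for (tt in trts) {
        ss <- s[s$treatment == tt, ]
        lines(ss$flush, ss$estimate, col = cols[tt], lwd = 2, type = "b", pch = 16)
      }
      legend("topleft", legend = trts, col = cols, lwd = 2, bty = "n")
      grDevices::dev.off()
      files <- c(files, path)
    }
    if (!is.null(report$contrasts)) {
      for (par in c("A", "B")) {
        path <- file.path(dir, sprintf("contrast_%s.png", par))
        grDevices::png(path, width = 900, height = 600)
        s <- report$contrasts[report$contrasts$parameter == par, ]
        trts <- sort(unique(s$treatment))
        cols <- stats::setNames(grDevices::hcl.colors(length(trts), "Dark 2"), trts)
        off <- stats::setNames(seq(-0.2, 0.2, length.out = length(trts)), trts)
        plot(range(s$flush) + c(-0.5, 0.5), range(c(s$lower, s$upper, 0)),
             type = "n", xlab = "flush",
             ylab = paste("difference vs control in", par),
             main = paste("Treatment contrasts:", par))
        abline(h = 0, lty = 2, col = "grey50")
        for (tt in trts) {
          ss <- s[s$treatment == tt, ]
          x <- ss$flush + off[tt]
          points(x, ss$difference, col = cols[tt], pch = 16)
          segments(x, ss$lower, x, ss$upper, col = cols[tt], lwd = 2)
        }
        legend("topright", legend = trts, col = cols, pch = 16, bty = "n")
        grDevices::dev.off()
        files <- c(files, path)
      }
    }
    files
  }, error = function(e) {
    warning("plotting skipped: ", conditionMessage(e))
    files
  })
  invisible(res)
}
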