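#' Configuration for flush-boundary detection
#'
#' @param method Smoother for the pooled cumulative series: `"gam"`
#'   (penalized thin-plate-style spline, smoothness by GCV) or `"loess"`.
#' @param gam_basis_dim Spline basis dimension (k) for the GAM smoother.
#' @param loess_span LOESS span (fraction of points in each local fit).
#' @param rolling_window Width (days, odd) of the centered rolling mean
#'   applied to the daily differences of the smoothed fit.
#' @param candidate_window_halfwidth Half-width (days) of the search window
#'   around each candidate rate minimum; candidates closer together than
#'   this are merged, keeping the deeper one.
#' @param expected_minima Optional expected number of interior minima; if
#'   given, a warning is raised when the detected count differs.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("gam", "loess"),
                                gam_basis_dim = 18,
                                loess_span = 0.1,
                                rolling_window = 7,
                                candidate_window_halfwidth = 30,
                                expected_minima = NULL) {
  method <- match.arg(method)
  stopifnot(gam_basis_dim >= 4, loess_span > 0, loess_span <= 1,
            rolling_window >= 1, rolling_window %% 2 == 1,
            candidate_window_halfwidth >= 1)
  structure(list(method = method, gam_basis_dim = gam_basis_dim,
                 loess_span = loess_span, rolling_window = rolling_window,
                 candidate_window_halfwidth = candidate_window_halfwidth,
                 expected_minima = expected_minima),
            class = "segmentation_config")
}

#' Pool daily yield over all beds
#'
#' Sums the daily counts of every bed into one series and accumulates it.
#' Leading all-zero days (before the first harvest) are trimmed by default,
#' since the day of first harvest is the natural origin of the analysis.
#'
#' @param yield_table A validated yield data frame.
#' @param trim_leading_zeros Drop days before the first harvested stem?
#' @return Data frame `day`, `daily`, `cumulative` (one row per day), with
#'   attribute `first_harvest_day`.
#' @export
pool_series <- function(yield_table, trim_leading_zeros = TRUE) {
  if (is.null(yield_table) || nrow(yield_table) == 0)
    stop("empty yield table")
  agg <- stats::aggregate(stems ~ day, data = yield_table, FUN = sum)
  agg <- agg[order(agg$day), ]
  first <- if (any(agg$stems > 0)) agg$day[which(agg$stems > 0)[1]] else agg$day[1]
  if (trim_leading_zeros) agg <- agg[agg$day >= first, , drop = FALSE]
  out <- data.frame(day = agg$day, daily = agg$stems,
                    cumulative = cumsum(agg$stems))
  attr(out, "first_harvest_day") <- first
  out
}

#' Smooth a pooled cumulative series
#'
#' Fits the overall trend of the pooled cumulative yield with either a
#' penalized spline regression (basis dimension `gam_basis_dim`,
#' smoothing parameter by generalized cross-validation) or a locally
#' weighted regression (LOESS, span `loess_span`).
#'
#' @param pooled Output of [pool_series()].
#' @param config A [segmentation_config()].
#' @return Data frame `day`, `fitted` with one row per observed day.
#' @export
smooth_cumulative <- function(pooled, config = segmentation_config()) {
  n <- nrow(pooled)
  if (config$method == "gam") {
    if (n <= config$gam_basis_dim)
      stop("series too short for gam smoothing: need more than ",
           config$gam_basis_dim, " days, got ", n)
    fit <- mgcv::gam(cumulative ~ s(day, k = config$gam_basis_dim, bs = "tp"),
                     data = pooled)
    fitted <- as.numeric(stats::fitted(fit))
  } else {
    if (config$loess_span * n < 3)
      stop("series too short for loess smoothing: need at least ",
           ceiling(3 / config$loess_span), " days, got ", n)
    fit <- stats::loess(cumulative ~ day, data = pooled,
                        span = config$loess_span, degree = 2)
    fitted <- as.numeric(stats::fitted(fit))
  }
  data.frame(day = pooled$day, fitted = fitted)
}

#' Daily differences of a smoothed fit
#'
#' @param smoothed Output of [smooth_cumulative()].
#' @return Data frame `day`, `rate` of length `n - 1`; the difference over
#'   `(d-1, d]` is assigned to day `d`.
#' @export
daily_change <- function(smoothed) {
  stopifnot(nrow(smoothed) >= 2)
  data.frame(day = smoothed$day[-1], rate = diff(smoothed$fitted))
}

#' Centered rolling mean with shrinking edge windows
#'
#' Averages each value with its neighbours in a centered window of
#' `window` days; at the series edges the window shrinks symmetrically to
#' the available points rather than padding, so no data are invented.
#'
#' @param x Numeric vector.
#' @param window Odd window width (days).
#' @return Numeric vector of the same length.
#' @export
rolling_mean <- function(x, window = 7) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (length(x) < window)
    stop("series shorter than the rolling window (", window, " days)")
  as.numeric(zoo::rollapply(x, window, mean, partial = TRUE, align = "center"))
}

#' Locate flush boundaries as local minima of the harvest rate
#'
#' Candidate boundaries are the interior local minima of the (rolled)
#' rate series; plateaus count once, at their earliest day. Candidates
#' closer together than `candidate_window_halfwidth` days are merged,
#' keeping the deeper one. Each retained candidate is then refined to the
#' day of minimal rate within its centered window of twice the half-width
#' (ties broken toward the earlier day).
#'
#' @param rate Data frame `day`, `rate` (smoothed daily harvest rate).
#' @param config A [segmentation_config()].
#' @return Integer-valued vector of boundary days (possibly empty, with a
#'   warning when no interior minimum exists).
#' @export
find_boundaries <- function(rate, config = segmentation_config()) {
  v <- rate$rate
  days <- rate$day
  cand <- local_minima_idx(v)
  if (!length(cand)) {
    warning("no interior local minima found; returning zero boundaries")
    return(numeric(0))
  }
  hw <- config$candidate_window_halfwidth
  # merge close candidates, keeping the deeper (lower-rate) one
  cand <- cand[order(days[cand])]
  repeat {
    if (length(cand) < 2) break
    gaps <- diff(days[cand])
    j <- which(gaps < hw)
    if (!length(j)) break
    j <- j[1]
    drop <- if (v[cand[j]] <= v[cand[j + 1]]) j + 1 else j
    cand <- cand[-drop]
  }
  # refine: argmin of the rate within +/- hw of each retained candidate
  refined <- vapply(cand, function(i) {
    win <- which(days >= days[i] - hw & days <= days[i] + hw)
    win[which.min(v[win])]  # which.min ties -> earliest
  }, integer(1))
  out <- sort(unique(days[refined]))
  if (!is.null(config$expected_minima) && length(out) != config$expected_minima)
    warning("detected ", length(out), " boundaries, expected ",
            config$expected_minima)
  out
}

# Interior local minima indices of a numeric vector, plateaus collapsing to
# their first index; the first and last runs never qualify.
local_minima_idx <- function(v) {
  r <- rle(v)
  if (length(r$values) < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  j <- 2:(length(r$values) - 1)
  keep <- r$values[j] < r$values[j - 1] & r$values[j] < r$values[j + 1]
  starts[j][keep]
}

#' Detect flush boundaries in a yield table
#'
#' End-to-end segmentation: pool the beds, smooth the cumulative series,
#' difference, roll, and locate rate minima. The first flush is taken to
#' start at the first harvest day rather than at a detected minimum.
#'
#' @param yield_table A validated yield data frame.
#' @param config A [segmentation_config()].
#' @return An object of class `flush_boundaries`: list with `boundary_days`
#'   (start day of every flush, first element = first harvest day),
#'   `offsets` (per-bed cumulative yield already harvested when each flush
#'   starts), `rate` (the smoothed rate series) and `config`.
#' @export
segment_flushes <- function(yield_table, config = segmentation_config()) {
  pooled <- pool_series(yield_table)
  sm <- smooth_cumulative(pooled, config)
  rt <- daily_change(sm)
  rt$rate <- rolling_mean(rt$rate, config$rolling_window)
  minima <- find_boundaries(rt, config)
  first <- attr(pooled, "first_harvest_day")
  flush_boundaries(yield_table, c(first, minima[minima > first]),
                   config = config, rate = rt)
}

#' Construct a flush-boundaries object
#'
#' @param yield_table A validated yield data frame.
#' @param boundary_days Strictly increasing start days, one per flush.
#' @param config Optional [segmentation_config()] used to find them.
#' @param rate Optional smoothed rate series (diagnostics).
#' @return An object of class `flush_boundaries`.
#' @export
flush_boundaries <- function(yield_table, boundary_days, config = NULL,
                             rate = NULL) {
  stopifnot(length(boundary_days) >= 1,
            !is.unsorted(boundary_days, strictly = TRUE))
  rng <- range(yield_table$day)
  if (boundary_days[1] < rng[1] || boundary_days[length(boundary_days)] > rng[2])
    stop("boundary days outside the data's day range")
  beds <- unique(yield_table$bed_id)
  offsets <- vapply(boundary_days, function(tk) {
    vapply(beds, function(b) {
      sub <- yield_table[yield_table$bed_id == b & yield_table$day < tk, ]
      if (nrow(sub) == 0) 0 else max(sub$cumulative)
    }, numeric(1))
  }, numeric(length(beds)))
  offsets <- matrix(offsets, nrow = length(beds),
                    dimnames = list(beds, paste0("flush", seq_along(boundary_days))))
  structure(list(boundary_days = boundary_days, offsets = offsets,
                 config = config, rate = rate),
            class = "flush_boundaries")
}

#' @export
print.flush_boundaries <- function(x, ...) {
  cat("Flush boundaries (", length(x$boundary_days), " flushes): ",
      paste(x$boundary_days, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Root-mean-square shift between two boundary sets
#'
#' The displacement metric of the sensitivity analysis: the RMS of the
#' pairwise day differences between two boundary vectors of equal length.
#' Identical sets give 0; a uniform shift of d days gives |d|.
#'
#' @param days Candidate boundary days.
#' @param reference Reference boundary days (same length).
#' @return A single non-negative number.
#' @export
boundary_rmse <- function(days, reference) {
  if (length(days) != length(reference))
    stop("boundary sets differ in length (", length(days), " vs ",
         length(reference), "); counts must match before comparing shifts")
  sqrt(mean((days - reference)^2))
}

#' Sensitivity of boundary placement to the smoothing parameters
#'
#' Re-runs boundary detection over a grid of GAM basis dimensions and
#' LOESS spans and measures, for every setting that yields the same number
#' of boundaries as the reference, the root-mean-square shift of the
#' boundary days relative to the reference setting. Settings with a
#' different boundary count are flagged and excluded from the RMSE
#' comparison. The recommended setting is the one whose neighbourhood
#' (itself and the adjacent grid values of the same method) has the lowest
#' mean RMSE.
#'
#' @param pooled Output of [pool_series()].
#' @param gam_dims Grid of GAM basis dimensions.
#' @param spans Grid of LOESS spans.
#' @param reference A [segmentation_config()] used as the reference.
#' @seealso [boundary_rmse()] for the shift metric.
#' @return An object of class `sensitivity_report`: list with `grid` (data
#'   frame `method`, `parameter`, `n_boundaries`, `comparable`, `rmse`),
#'   `boundaries` (list of day vectors), `reference_days` and
#'   `recommended` (row index into `grid`).
#' @export
sensitivity_analysis <- function(pooled,
                                 gam_dims = c(12, 15, 18, 21),
                                 spans = c(0.05, 0.1, 0.15, 0.2),
                                 reference = segmentation_config()) {
  run_one <- function(cfg) {
    sm <- smooth_cumulative(pooled, cfg)
    rt <- daily_change(sm)
    rt$rate <- rolling_mean(rt$rate, cfg$rolling_window)
    suppressWarnings(find_boundaries(rt, cfg))
  }
  ref_days <- run_one(reference)
  grid <- rbind(
    data.frame(method = "gam", parameter = gam_dims),
    data.frame(method = "loess", parameter = spans)
  )
  bnds <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- reference
    cfg$method <- grid$method[i]
    if (grid$method[i] == "gam") cfg$gam_basis_dim <- grid$parameter[i]
    else cfg$loess_span <- grid$parameter[i]
    bnds[[i]] <- tryCatch(run_one(cfg), error = function(e) numeric(0))
  }
  grid$n_boundaries <- vapply(bnds, length, integer(1))
  grid$comparable <- grid$n_boundaries == length(ref_days)
  grid$rmse <- NA_real_
  grid$rmse[grid$comparable] <- vapply(bnds[grid$comparable], boundary_rmse,
                                       numeric(1), reference = ref_days)
  if (!any(grid$comparable))
    stop("no grid setting produced the reference boundary count")
  # neighbourhood mean RMSE within each method's grid
  nb <- rep(NA_real_, nrow(grid))
  for (m in unique(grid$method)) {
    idx <- which(grid$method == m)
    idx <- idx[order(grid$parameter[idx])]
    for (j in seq_along(idx)) {
      neigh <- idx[max(1, j - 1):min(length(idx), j + 1)]
      r <- grid$rmse[neigh]
      nb[idx[j]] <- if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
    }
  }
  grid$neighbourhood_rmse <- nb
  ok <- which(grid$comparable & !is.na(nb))
  recommended <- ok[which.min(nb[ok])]
  structure(list(grid = grid, boundaries = bnds, reference_days = ref_days,
                 reference = reference, recommended = recommended),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Boundary sensitivity analysis (reference: ",
      x$reference$method, ")\n", sep = "")
  print(x$grid, row.names = FALSE)
  rec <- x$grid[x$recommended, ]
  cat("recommended:", rec$method, "with parameter", rec$parameter, "\n")
  invisible(x)
}

#' Split a yield table into per-flush transformed series
#'
#' For flush k and bed i, re-expresses each observation in flush-local
#' coordinates: `tprime = day - t_k` and `yprime = cumulative - y_k(i)`,
#' where `y_k(i)` is the bed's cumulative harvest before the flush starts.
#' Flush k covers days `[t_k, t_{k+1})`; the last flush runs to the final
#' observed day. Days before the first boundary are dropped.
#'
#' @param yield_table A validated yield data frame.
#' @param boundaries A [flush_boundaries()] object.
#' @return Data frame with columns `flush`, `bed_id`, `block_id`,
#'   `treatment`, `day`, `tprime`, `stems`, `cumulative`, `yprime`.
#' @export
split_flushes <- function(yield_table, boundaries) {
  stopifnot(inherits(boundaries, "flush_boundaries"))
  days <- boundaries$boundary_days
  ends <- c(days[-1] - 1, max(yield_table$day))
  out <- lapply(seq_along(days), function(k) {
    sub <- yield_table[yield_table$day >= days[k] & yield_table$day <= ends[k], ,
                       drop = FALSE]
    sub$flush <- k
    sub$tprime <- sub$day - days[k]
    sub$yprime <- sub$cumulative - boundaries$offsets[sub$bed_id, k]
    sub
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("flush", "bed_id", "block_id", "treatment", "day", "tprime",
          "stems", "cumulative", "yprime")]
}

#' Observation weights down-weighting a harvest-pause artifact
#'
#' Days inside the pause and its catch-up period carry a low weight so
#' model fits rely on the undistorted beginning and end of the flush; all
#' other observations get weight 1.
#'
#' @param flush_data A data frame with a `day` column (typically one flush
#'   of [split_flushes()] output).
#' @param pause Optional [pause_spec()]; `NULL` gives all-ones weights.
#' @param low_weight Weight assigned inside `[pause_start, catchup_end]`.
#' @return Numeric weight vector, one per row of `flush_data`.
#' @export
build_weights <- function(flush_data, pause = NULL, low_weight = 0.01) {
  w <- rep(1, nrow(flush_data))
  if (!is.null(pause)) {
    stopifnot(inherits(pause, "pause_spec"))
    w[flush_data$day >= pause$pause_start &
        flush_data$day <= pause$catchup_end] <- low_weight
  }
  w
}
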