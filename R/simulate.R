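#' Experimental design of a multi-flush yield trial
#'
#' Describes a randomized block design with one bed (the experimental and
#' repeated-measures unit, ~500 plants) per block-by-treatment combination.
#' The default mirrors a commercial greenhouse trial: five treatments
#' (three compost amendments, one compost + halved fertigation, one
#' untreated control) replicated in three blocks, i.e. 15 beds, observed
#' daily for 560 days after planting.
#'
#' @param n_blocks Number of blocks (>= 1).
#' @param treatments Character vector of unique treatment labels.
#' @param plants_per_bed Plants per bed (metadata only).
#' @param planting_day Day index of planting (origin of the day axis).
#' @param horizon Number of observed days; records cover days
#'   `planting_day` to `planting_day + horizon - 1`.
#' @return An object of class `experiment_design`: a list with the fields
#'   above plus `beds`, a data frame with one row per bed
#'   (`bed_id`, `block_id`, `treatment`).
#' @export
experiment_design <- function(n_blocks = 3,
                              treatments = c("R", "T", "C", "R50", "Control"),
                              plants_per_bed = 500,
                              planting_day = 0,
                              horizon = 560) {
  stopifnot(n_blocks >= 1, length(treatments) >= 1,
            !anyDuplicated(treatments), horizon > 0)
  beds <- expand.grid(block_id = paste0("block", seq_len(n_blocks)),
                      treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  beds$bed_id <- sprintf("bed%02d", seq_len(nrow(beds)))
  structure(list(n_blocks = n_blocks, treatments = treatments,
                 plants_per_bed = plants_per_bed,
                 planting_day = planting_day, horizon = horizon,
                 beds = beds[, c("bed_id", "block_id", "treatment")]),
            class = "experiment_design")
}

#' Ground-truth parameters of one flowering flush
#'
#' Holds the generating Gompertz parameters of the k-th flush. `A` and `B`
#' may be named per treatment (names matching the design's treatment
#' labels) or a single value shared by all treatments. Random effects are
#' additive on the natural scale: blocks perturb `A` (and optionally `B`),
#' beds perturb `A` and `B`; `C` is common to all beds within a flush.
#'
#' @param k 1-based flush index.
#' @param start_day Day (since planting) at which the flush starts.
#' @param A,B Per-treatment asymptote (stems) and growth-rate parameter.
#' @param C Horizontal-shift rate (per day), shared within the flush.
#' @param sigma_block_A,sigma_block_B SDs of block random effects.
#' @param sigma_bed_A,sigma_bed_B SDs of bed random effects.
#' @param noise_sd SD (stems) of daily observation noise added to the
#'   harvest increments before integer rounding.
#' @return An object of class `flush_truth`.
#' @export
flush_truth <- function(k, start_day, A, B, C = 0.1,
                        sigma_block_A = 50, sigma_block_B = 0,
                        sigma_bed_A = 80, sigma_bed_B = 0.1,
                        noise_sd = 5) {
  stopifnot(k >= 1, start_day >= 0, all(A > 0), C > 0,
            sigma_block_A >= 0, sigma_block_B >= 0,
            sigma_bed_A >= 0, sigma_bed_B >= 0, noise_sd >= 0)
  structure(list(k = k, start_day = start_day, A = A, B = B, C = C,
                 sigma_block_A = sigma_block_A, sigma_block_B = sigma_block_B,
                 sigma_bed_A = sigma_bed_A, sigma_bed_B = sigma_bed_B,
                 noise_sd = noise_sd),
            class = "flush_truth")
}

#' Default ground truth: eight flushes of a maturing rose crop
#'
#' Start days follow the observed flush starts of an 18-month greenhouse
#' trial (first harvest on day 91, boundaries roughly every 50-65 days).
#' Control asymptotes rise from ~800 to ~3000 stems per bed with a dip in
#' the final flush; compost treatments carry an early-flush advantage that
#' fades as the crop matures, and the halved-fertigation treatment tracks
#' the compost treatments until flush 4 and then falls back to control
#' level. Growth rate `B` declines over flushes and is lowest in flush 1,
#' which starts at the first harvest day rather than a rate minimum.
#'
#' @param design An [experiment_design()].
#' @param start_days Flush start days (since planting), strictly increasing.
#' @param noise_sd Daily observation-noise SD passed to every flush.
#' @param sigma_block_A,sigma_bed_A,sigma_bed_B Random-effect SDs passed
#'   to every flush.
#' @return A list of [flush_truth()] objects.
#' @export
default_flush_truths <- function(design = experiment_design(),
                                 start_days = c(91, 129, 186, 240, 302, 363, 426, 490),
                                 noise_sd = 5,
                                 sigma_block_A = 50,
                                 sigma_bed_A = 80,
                                 sigma_bed_B = 0.1) {
  n <- length(start_days)
  stopifnot(n >= 1, !is.unsorted(start_days, strictly = TRUE))
  ctrl_A <- c(800, 1000, 1200, 2400, 2800, 3000, 3000, 2600)
  lift_full <- c(250, 300, 400, 500, 450, 350, 150, 100)   # compost + full fertigation
  lift_half <- c(250, 300, 400, 450, 150, 50, 0, 0)        # compost + halved fertigation
  ctrl_B <- c(1.8, 2.4, 2.35, 2.3, 2.2, 2.1, 2.05, 2.0)
  liftB <- c(0, 0.1, 0.1, 0.1, 0.1, 0.1, 0, 0)
  Cs <- c(0.16, rep(0.11, 7))
  idx <- function(x, k) x[((k - 1) %% length(x)) + 1]
  trts <- design$treatments
  lapply(seq_len(n), function(k) {
    a0 <- idx(ctrl_A, k)
    lf <- idx(lift_full, k)
    lh <- idx(lift_half, k)
    scale_full <- c(1, 0.9, 0.8)  # R, T, C ordering of the compost lift
    A <- vapply(seq_along(trts), function(j) {
      lab <- trts[j]
      if (lab == "Control") a0
      else if (grepl("50", lab)) a0 + lh
      else a0 + lf * scale_full[((j - 1) %% 3) + 1]
    }, numeric(1))
    b0 <- idx(ctrl_B, k)
    lb <- idx(liftB, k)
    B <- vapply(trts, function(lab) {
      if (lab == "Control") b0 else b0 + lb
    }, numeric(1))
    names(A) <- names(B) <- trts
    flush_truth(k = k, start_day = start_days[k], A = A, B = B,
                C = idx(Cs, k),
                sigma_block_A = sigma_block_A,
                sigma_bed_A = sigma_bed_A, sigma_bed_B = sigma_bed_B,
                noise_sd = noise_sd)
  })
}

#' Harvest-pause artifact specification
#'
#' An interval of zero recorded harvest followed by a catch-up period that
#' receives the deferred stems, emulating an unplanned pause in harvesting
#' operations. Days are absolute (since planting), both endpoints included.
#'
#' @param pause_start,pause_end First and last day with no harvest.
#' @param catchup_end Last day of the catch-up period
#'   (`pause_end < catchup_end` unless the catch-up is a single day).
#' @return An object of class `pause_spec`.
#' @export
pause_spec <- function(pause_start = 201, pause_end = 213, catchup_end = 220) {
  stopifnot(pause_start < pause_end, pause_end <= catchup_end)
  structure(list(pause_start = pause_start, pause_end = pause_end,
                 catchup_end = catchup_end),
            class = "pause_spec")
}

#' Simulate daily harvest counts for one bed over one flush
#'
#' Generates integer daily counts whose expected cumulative sum follows the
#' Gompertz curve with the bed's realized parameters
#' `A_i = A_true + block + bed` and `B_i` analogous. Gaussian noise of SD
#' `flush$noise_sd` is added to each daily increment; increments are then
#' rounded, clipped at zero, and the rounding/clipping residual is carried
#' forward to the next day so the flush total is preserved.
#'
#' @param flush A [flush_truth()] object.
#' @param A_i,B_i Realized (random-effect adjusted) parameters of this bed.
#' @param days Absolute day indices covered by the flush, starting at
#'   `flush$start_day`.
#' @param seed Optional RNG seed for this bed-flush substream.
#' @return Integer vector of daily counts, one per element of `days`.
#' @export
simulate_bed_flush <- function(flush, A_i, B_i, days, seed = NULL) {
  stopifnot(inherits(flush, "flush_truth"), length(days) >= 1,
            days[1] == flush$start_day)
  if (A_i <= 0) stop("realized asymptote A_i must be positive")
  tprime <- days - flush$start_day
  mu <- gompertz(tprime, A_i, B_i, flush$C)
  inc <- diff(c(0, mu))  # day-0 increment collects mass up to flush start
  with_seed(seed, {
    noise <- if (flush$noise_sd > 0) stats::rnorm(length(inc), 0, flush$noise_sd) else 0
    raw <- inc + noise
    counts <- integer(length(raw))
    carry <- 0
    for (j in seq_along(raw)) {
      x <- raw[j] + carry
      counts[j] <- max(0L, as.integer(round(x)))
      carry <- x - counts[j]
    }
    counts
  })
}

#' Simulate a complete randomized-block multi-flush experiment
#'
#' Draws block and bed random effects per flush, simulates every bed-flush
#' series with [simulate_bed_flush()], concatenates flushes along the day
#' axis (flush k covers `[t_k, t_{k+1})`, the last flush runs to the
#' horizon) and optionally injects a harvest-pause artifact. A single seed
#' governs the experiment; per-bed-flush substreams are derived from it
#' deterministically, so results are reproducible.
#'
#' @param design An [experiment_design()].
#' @param flushes List of [flush_truth()] objects with strictly increasing
#'   start days inside the horizon.
#' @param pause Optional [pause_spec()]; deferred stems are redistributed
#'   evenly over the catch-up days so each flush total is unchanged.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_dataset`: a list with
#'   \describe{
#'     \item{yield}{data frame `bed_id`, `block_id`, `treatment`, `day`,
#'       `stems`, `cumulative` covering every bed and every day.}
#'     \item{truth}{generating parameters: the `flushes` list, realized
#'       block/bed effects per flush, the seed and the design.}
#'   }
#' @export
simulate_experiment <- function(design = experiment_design(),
                                flushes = default_flush_truths(design),
                                pause = NULL, seed = 1) {
  stopifnot(inherits(design, "experiment_design"), length(flushes) >= 1)
  starts <- vapply(flushes, `[[`, numeric(1), "start_day")
  if (is.unsorted(starts, strictly = TRUE))
    stop("flush start days must be strictly increasing (overlapping flush windows)")
  last_day <- design$planting_day + design$horizon - 1
  if (starts[1] < design$planting_day || starts[length(starts)] > last_day)
    stop("flush start days must lie within the observation horizon")

  beds <- design$beds
  n_beds <- nrow(beds)
  n_fl <- length(flushes)
  blocks <- unique(beds$block_id)

  sub_seeds <- derive_seeds(seed, n_beds * n_fl + 1L)
  effect_seed <- sub_seeds[length(sub_seeds)]

  # realized random effects, redrawing any bed whose asymptote would be <= 0
  effects <- with_seed(effect_seed, {
    lapply(seq_len(n_fl), function(k) {
      fl <- flushes[[k]]
      blk <- data.frame(block_id = blocks,
                        block_A = stats::rnorm(length(blocks), 0, fl$sigma_block_A),
                        block_B = stats::rnorm(length(blocks), 0, fl$sigma_block_B),
                        stringsAsFactors = FALSE)
      bed <- beds
      bed$bed_A <- stats::rnorm(n_beds, 0, fl$sigma_bed_A)
      bed$bed_B <- stats::rnorm(n_beds, 0, fl$sigma_bed_B)
      bed <- merge(bed, blk, by = "block_id", sort = FALSE)
      A_t <- flush_param(fl$A, bed$treatment)
      B_t <- flush_param(fl$B, bed$treatment)
      bed$A_i <- A_t + bed$block_A + bed$bed_A
      bed$B_i <- B_t + bed$block_B + bed$bed_B
      bad <- which(bed$A_i <= 0)
      tries <- 0
      while (length(bad) && tries < 100) {
        warning("redrawing ", length(bad), " bed effect(s) with non-positive asymptote")
        bed$bed_A[bad] <- stats::rnorm(length(bad), 0, fl$sigma_bed_A)
        bed$A_i[bad] <- A_t[bad] + bed$block_A[bad] + bed$bed_A[bad]
        bad <- which(bed$A_i <= 0)
        tries <- tries + 1
      }
      if (length(bad)) stop("could not realize a positive asymptote for some beds")
      bed
    })
  })

  all_days <- design$planting_day:last_day
  ends <- c(starts[-1] - 1, last_day)

  per_bed <- lapply(seq_len(n_beds), function(i) {
    counts <- integer(length(all_days))
    for (k in seq_len(n_fl)) {
      fl <- flushes[[k]]
      days_k <- fl$start_day:ends[k]
      eff <- effects[[k]]
      row <- eff[eff$bed_id == beds$bed_id[i], ]
      ck <- simulate_bed_flush(fl, row$A_i, row$B_i, days_k,
                               seed = sub_seeds[(k - 1) * n_beds + i])
      counts[match(days_k, all_days)] <- ck
    }
    if (!is.null(pause)) counts <- apply_pause(counts, all_days, pause)
    data.frame(bed_id = beds$bed_id[i], block_id = beds$block_id[i],
               treatment = beds$treatment[i], day = all_days,
               stems = counts, cumulative = cumsum(counts),
               stringsAsFactors = FALSE)
  })
  yield <- do.call(rbind, per_bed)
  rownames(yield) <- NULL
  structure(list(yield = yield,
                 truth = list(flushes = flushes, effects = effects,
                              seed = seed, design = design, pause = pause)),
            class = "synthetic_dataset")
}

# Expand a (possibly scalar or named) per-treatment parameter to bed order.
flush_param <- function(p, treatment) {
  if (length(p) == 1 && is.null(names(p))) return(rep(p, length(treatment)))
  if (is.null(names(p))) stop("per-treatment parameters must be named")
  if (!all(treatment %in% names(p)))
    stop("parameter names do not cover all treatments")
  unname(p[treatment])
}

# Zero the pause window and move the deferred stems into the catch-up days
# (even split, remainder to the earliest days) -- conserves the total exactly.
apply_pause <- function(counts, days, pause) {
  stopifnot(inherits(pause, "pause_spec"))
  in_pause <- days >= pause$pause_start & days <= pause$pause_end
  catchup <- which(days > pause$pause_end & days <= pause$catchup_end)
  if (!any(in_pause) || !length(catchup)) return(counts)
  deferred <- sum(counts[in_pause])
  counts[in_pause] <- 0L
  base <- deferred %/% length(catchup)
  extra <- deferred %% length(catchup)
  add <- rep(base, length(catchup))
  if (extra > 0) add[seq_len(extra)] <- add[seq_len(extra)] + 1L
  counts[catchup] <- counts[catchup] + as.integer(add)
  counts
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic multi-flush yield experiment\n")
  cat("  beds:", length(unique(x$yield$bed_id)),
      " days:", length(unique(x$yield$day)),
      " flushes:", length(x$truth$flushes),
      " seed:", x$truth$seed, "\n")
  invisible(x)
}
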