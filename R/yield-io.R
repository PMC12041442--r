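#' Write a daily yield table to CSV
#'
#' Writes the long-format daily harvest records (one row per bed and day)
#' with columns `bed_id`, `block_id`, `treatment`, `day`, `stems`. The
#' derived `cumulative` column is not written; readers recompute it.
#'
#' @param x A `synthetic_dataset` or a yield data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_yield_csv <- function(x, path) {
  tab <- if (inherits(x, "synthetic_dataset")) x$yield else x
  validate_yield_series(tab)
  utils::write.csv(tab[, c("bed_id", "block_id", "treatment", "day", "stems")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily yield table from CSV
#'
#' Expects columns `bed_id`, `block_id`, `treatment`, `day`, `stems`;
#' validates that counts are non-negative integers, that no (bed, day) pair
#' is duplicated and that each bed covers a gap-free day range, then adds
#' the per-bed `cumulative` column.
#'
#' @param path CSV file path.
#' @return A validated yield data frame ordered by bed and day.
#' @export
read_yield_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_yield_series(tab)
}

#' Validate a daily yield table
#'
#' Checks the structural invariants of a yield series (required columns,
#' integer non-negative counts, unique and gap-free days per bed) and
#' returns the table ordered by `bed_id` and `day` with a per-bed
#' `cumulative` column appended.
#'
#' @param tab A data frame of daily harvest records.
#' @return The validated, ordered table.
#' @export
validate_yield_series <- function(tab) {
  need <- c("bed_id", "block_id", "treatment", "day", "stems")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("yield table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0) stop("yield table is empty")
  bad <- which(!is.finite(tab$stems) | tab$stems < 0 | tab$stems != round(tab$stems))
  if (length(bad))
    stop("stems must be non-negative integers; first offending row: bed ",
         tab$bed_id[bad[1]], ", day ", tab$day[bad[1]],
         ", stems ", tab$stems[bad[1]])
  tab <- tab[order(tab$bed_id, tab$day), , drop = FALSE]
  dup <- duplicated(tab[, c("bed_id", "day")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate (bed, day) row: bed ", tab$bed_id[i], ", day ", tab$day[i])
  }
  for (b in unique(tab$bed_id)) {
    d <- tab$day[tab$bed_id == b]
    gaps <- which(diff(d) != 1)
    if (length(gaps))
      stop("day gap in bed ", b, " between day ", d[gaps[1]],
           " and day ", d[gaps[1] + 1])
  }
  tab$cumulative <- stats::ave(tab$stems, tab$bed_id, FUN = cumsum)
  rownames(tab) <- NULL
  tab
}

#' Write the generating truth of a synthetic dataset to JSON
#'
#' Sidecar file recording the flush parameters, realized random effects,
#' design and seed, so recovery analyses can be run against known truth.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  tr <- dataset$truth
  out <- list(
    seed = tr$seed,
    design = list(n_blocks = tr$design$n_blocks,
                  treatments = tr$design$treatments,
                  horizon = tr$design$horizon,
                  beds = tr$design$beds),
    pause = if (!is.null(tr$pause)) unclass(tr$pause),
    flushes = lapply(tr$flushes, unclass),
    effects = tr$effects
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
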