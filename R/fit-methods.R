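#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz mixed-model fit (", x$estimator, ")\n", sep = "")
  cat("  observations:", x$n_obs,
      " Efron R^2:", round(x$r2, 4),
      if (x$weighted) " [weighted]" else "", "\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Population-level parameter table across flushes
#'
#' Collects the treatment-level estimates (random effects at their mean,
#' zero) of a list of per-flush Gompertz fits into one long table keyed by
#' flush, treatment and parameter. `C` is shared within a flush and
#' appears once per flush with `treatment = NA`.
#'
#' @param fits A list of `gompertz_fit` objects (or a single fit). Names or
#'   a `flush` attribute give the flush index; otherwise list position is
#'   used.
#' @return Data frame `flush`, `treatment`, `parameter`, `estimate`, `se`,
#'   `estimator`, `r2`.
#' @export
treatment_table <- function(fits) {
  if (inherits(fits, "gompertz_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  out <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    idx <- attr(f, "flush") %||% k
    cbind(flush = idx, f$estimates, estimator = f$estimator, r2 = f$r2)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("flush", "treatment", "parameter", "estimate", "se",
          "estimator", "r2")]
}

#' Per-flush treatment contrasts against the control
#'
#' Differences `estimate(treatment) - estimate(control)` in `A` and `B`
#' per flush, with Wald confidence intervals. When the fits carry a joint
#' fixed-effect covariance the SE of a difference uses the full
#' `Var(t) + Var(c) - 2 Cov(t, c)`; when only marginal SEs are available
#' (a plain treatment table) the covariance term is set to zero and the
#' output flags this with `covariance_used = FALSE`.
#'
#' @param fits A list of `gompertz_fit` objects, a single fit, or a
#'   [treatment_table()] data frame.
#' @param control Control treatment label, present in every flush.
#' @param alpha Two-sided error rate of the Wald interval (default 0.05,
#'   i.e. 95% confidence).
#' @return Data frame `flush`, `treatment`, `parameter`, `difference`,
#'   `se`, `lower`, `upper`, `significant`, `covariance_used`. The control
#'   itself is excluded.
#' @export
contrast_vs_control <- function(fits, control = "Control", alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  if (is.data.frame(fits)) {
    tab <- fits
    vcovs <- NULL
  } else {
    if (inherits(fits, "gompertz_fit")) fits <- list(fits)
    tab <- treatment_table(fits)
    vcovs <- stats::setNames(lapply(fits, `[[`, "vcov"), unique(tab$flush))
  }
  tab <- tab[tab$parameter %in% c("A", "B"), ]
  out <- list()
  for (k in unique(tab$flush)) {
    sub <- tab[tab$flush == k, ]
    if (!control %in% sub$treatment)
      stop("control treatment '", control, "' missing in flush ", k)
    for (par in c("A", "B")) {
      s <- sub[sub$parameter == par, ]
      ctrl <- s[s$treatment == control, ]
      for (i in which(s$treatment != control)) {
        diff <- s$estimate[i] - ctrl$estimate
        if (!is.null(vcovs)) {
          V <- vcovs[[as.character(k)]]
          ni <- paste0(par, "_", s$treatment[i])
          nc <- paste0(par, "_", control)
          se <- sqrt(V[ni, ni] + V[nc, nc] - 2 * V[ni, nc])
          covu <- TRUE
        } else {
          se <- sqrt(s$se[i]^2 + ctrl$se^2)
          covu <- FALSE
        }
        out[[length(out) + 1]] <- data.frame(
          flush = k, treatment = s$treatment[i], parameter = par,
          difference = diff, se = se,
          lower = diff - z * se, upper = diff + z * se,
          significant = (diff - z * se) > 0 | (diff + z * se) < 0,
          covariance_used = covu)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
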