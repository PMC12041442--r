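#' Gompertz growth curve
#'
#' Evaluates the three-parameter Gompertz sigmoid
#' \deqn{y(t) = A \exp(-\exp(B - C t))}
#' where `A` is the upper asymptote (maximum cumulative harvest, stems),
#' `B` a dimensionless growth-rate parameter and `C` (per day) the
#' horizontal-shift rate. The curve is strictly increasing in `t` with a
#' single inflection at `t = B/C`, where it passes through `A/e`.
#'
#' @param t Numeric vector of times (days).
#' @param A Upper asymptote, `A > 0`.
#' @param B Growth-rate parameter (dimensionless).
#' @param C Horizontal-shift rate (per day), `C > 0`.
#' @return Numeric vector of predicted cumulative values, same length as `t`.
#' @examples
#' gompertz(20, A = 1000, B = 2, C = 0.1)  # inflection: 1000 / e
#' @export
gompertz <- function(t, A, B, C) {
  stopifnot(is.numeric(t), all(A > 0), all(C > 0))
  A * exp(-exp(B - C * t))
}

#' Efron's R-squared
#'
#' Squared-error goodness of fit applicable to any predictor:
#' \eqn{1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}.
#'
#' @param observed Numeric vector of observations.
#' @param fitted Numeric vector of predictions, same length.
#' @return A single number, at most 1. `NA` (with a warning) when the
#'   observations have zero variance, where the measure is undefined.
#' @export
efron_r2 <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("Efron's R^2 is undefined for constant observations")
    return(NA_real_)
  }
  1 - sum((observed - fitted)^2) / sst
}
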