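# Deterministic two-stage fallback estimator: per-bed weighted nonlinear
# least squares, then a linear mixed model (treatment fixed effect, block
# random intercept) on the per-bed parameter estimates. Intended for
# degenerate or very small data where the SAEM machinery is not warranted.

fit_flush_two_stage <- function(data, weights, spec) {
  ord <- order(data$bed_id, data$tprime)
  data <- data[ord, , drop = FALSE]
  weights <- weights[ord]
  beds <- unique(data[, c("bed_id", "block_id", "treatment")])
  beds <- beds[order(beds$bed_id), ]
  trts <- sort(unique(beds$treatment))

  st <- if (spec$start_values == "data") data_start(data, spec$start)
        else config_start(data, spec$start)

  pars <- lapply(seq_len(nrow(beds)), function(i) {
    sub <- data$bed_id == beds$bed_id[i]
    d <- data[sub, ]
    w <- weights[sub]
    s0 <- list(A = unname(st$A[beds$treatment[i]]),
               B = unname(st$B[beds$treatment[i]]), C = st$C)
    fit <- tryCatch(
      minpack.lm::nlsLM(yprime ~ A * exp(-exp(B - C * tprime)),
                        data = d, weights = w, start = s0,
                        lower = c(A = 1e-6, B = -10, C = 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    data.frame(beds[i, ], A = cf["A"], B = cf["B"], C = cf["C"],
               row.names = NULL)
  })
  ok <- !vapply(pars, is.null, logical(1))
  if (!any(ok)) stop("two-stage fit failed: no bed-level NLS fit converged")
  if (any(!ok))
    warning("dropping ", sum(!ok), " bed(s) whose NLS fit failed")
  pars <- do.call(rbind, pars[ok])
  pars$treatment <- factor(pars$treatment, levels = trts)

  stage2 <- function(resp) {
    fml <- stats::as.formula(paste(resp, "~ 0 + treatment"))
    fit <- NULL
    if (length(unique(pars$block_id)) >= 2)
      fit <- tryCatch(
        nlme::lme(fml, random = ~ 1 | block_id, data = pars,
                  control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
        error = function(e) NULL)
    if (is.null(fit)) {
      lmfit <- stats::lm(fml, data = pars)
      list(est = stats::coef(lmfit), vc = stats::vcov(lmfit),
           var_block = NA_real_, var_bed = stats::sigma(lmfit)^2)
    } else {
      vc1 <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
      list(est = nlme::fixef(fit), vc = stats::vcov(fit),
           var_block = vc1[1], var_bed = vc1[2])
    }
  }
  fa <- stage2("A")
  fb <- stage2("B")
  Cest <- mean(pars$C)
  Cse <- if (nrow(pars) > 1) stats::sd(pars$C) / sqrt(nrow(pars)) else 0

  p <- 2 * length(trts) + 1
  vc <- matrix(0, p, p)
  nm <- c(paste0("A_", trts), paste0("B_", trts), "C")
  dimnames(vc) <- list(nm, nm)
  vc[seq_along(trts), seq_along(trts)] <- as.matrix(fa$vc)
  vc[length(trts) + seq_along(trts), length(trts) + seq_along(trts)] <-
    as.matrix(fb$vc)
  vc[p, p] <- Cse^2

  A_t <- unname(fa$est); B_t <- unname(fb$est)
  est <- rbind(
    data.frame(parameter = "A", treatment = trts, estimate = A_t,
               se = sqrt(diag(as.matrix(fa$vc)))),
    data.frame(parameter = "B", treatment = trts, estimate = B_t,
               se = sqrt(diag(as.matrix(fb$vc)))),
    data.frame(parameter = "C", treatment = NA_character_, estimate = Cest,
               se = Cse)
  )
  rownames(est) <- NULL

  kept <- data$bed_id %in% pars$bed_id
  d <- data[kept, ]
  w <- weights[kept]
  i <- match(d$bed_id, pars$bed_id)
  fit_ind <- pars$A[i] * exp(-exp(pars$B[i] - pars$C[i] * d$tprime))
  j <- match(d$treatment, trts)
  fit_pop <- A_t[j] * exp(-exp(B_t[j] - Cest * d$tprime))

  structure(list(
    estimates = est,
    vcov = vc,
    var_components = c(bed_A = fa$var_bed, bed_B = fb$var_bed,
                       block_A = fa$var_block, block_B = fb$var_block,
                       residual = NA_real_),
    random_effects = list(bed = pars, block = NULL),
    fitted = data.frame(bed_id = d$bed_id, treatment = d$treatment,
                        tprime = d$tprime, yprime = d$yprime, weight = w,
                        fitted = fit_ind, fitted_population = fit_pop),
    r2 = efron_r2(d$yprime, fit_ind),
    r2_population = efron_r2(d$yprime, fit_pop),
    converged = TRUE,
    trace = NULL,
    loglik_trace = NULL,
    acceptance_rate = NA_real_,
    estimator = "two_stage",
    treatments = trts,
    spec = spec,
    n_obs = nrow(d),
    weighted = !all(weights == 1)
  ), class = "gompertz_fit")
}
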