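#' Specification of the per-flush Gompertz mixed-model fit
#'
#' Controls the nonlinear mixed-effects fit of the transformed Gompertz
#' curve: treatment-specific fixed effects on `A` and `B`, a shared `C`,
#' block and bed random effects on `A` and `B` (diagonal covariance), and
#' an additive normal residual with constant variance. Estimation is by
#' SAEM (stochastic approximation EM): an MCMC E-step samples the bed- and
#' block-level effects and a stochastic-approximation M-step updates the
#' population parameters; fixed-effect standard errors come from a
#' Louis-type stochastic approximation of the Fisher information.
#'
#' @param start Named numeric start values `c(A=, B=, C=)`.
#' @param start_values `"config"` uses `start` for every treatment;
#'   `"data"` derives starts from the data (`A0 = 1.05 max y'`, `C0` and
#'   `B0` from the linearising log(-log) regression), useful when the
#'   data's scale is far from the configured start.
#' @param block_effects `"AB"` puts block random effects on both `A` and
#'   `B`; `"A"` on the asymptote only. Ignored (no block effects) when the
#'   data contain a single block.
#' @param estimator `"saem"` or the deterministic `"two_stage"` fallback
#'   (per-bed nonlinear least squares followed by a linear mixed model on
#'   the per-bed parameter estimates), intended for degenerate or very
#'   small data.
#' @param n_burnin,n_smooth SAEM iteration counts for the exploration
#'   (step size 1) and smoothing (step size 1/m) phases.
#' @param n_mh Metropolis passes per SAEM iteration.
#' @param seed RNG seed making the SAEM fit reproducible.
#' @param convergence_window,convergence_tol The fit refuses to report when
#'   the normalised trend (|OLS slope| / |estimate|, per iteration) of any
#'   fixed-effect trace over the final `convergence_window` iterations
#'   exceeds `convergence_tol`.
#' @return An object of class `nlme_spec`.
#' @export
nlme_spec <- function(start = c(A = 1000, B = 2, C = 0.1),
                      start_values = c("config", "data"),
                      block_effects = c("AB", "A"),
                      estimator = c("saem", "two_stage"),
                      n_burnin = 300, n_smooth = 100, n_mh = 2,
                      seed = 1234,
                      convergence_window = 50, convergence_tol = 5e-4) {
  start_values <- match.arg(start_values)
  block_effects <- match.arg(block_effects)
  estimator <- match.arg(estimator)
  stopifnot(start["A"] > 0, start["C"] > 0,
            n_burnin > 0, n_smooth > 0, n_mh >= 1,
            convergence_window >= 2, convergence_tol > 0)
  structure(list(start = start, start_values = start_values,
                 block_effects = block_effects, estimator = estimator,
                 n_burnin = n_burnin, n_smooth = n_smooth, n_mh = n_mh,
                 seed = seed,
                 convergence_window = convergence_window,
                 convergence_tol = convergence_tol),
            class = "nlme_spec")
}

#' Fit the transformed Gompertz mixed model to one flush
#'
#' Fits `y' = A_i exp(-exp(B_i - C t')) + e` to the flush-local series of
#' all beds, where `A_i` and `B_i` decompose into a treatment fixed effect
#' plus block and bed random effects and `C` is shared across beds.
#' Weighted observations contribute `w` times their log-likelihood
#' (equivalently, residual variance `sigma^2 / w`), the semantics used to
#' down-weight harvest-pause artifacts.
#'
#' @param data Data frame with columns `bed_id`, `block_id`, `treatment`,
#'   `tprime`, `yprime` covering a single flush.
#' @param weights Optional per-observation weights (default all ones).
#' @param spec An [nlme_spec()].
#' @return An object of class `gompertz_fit`; see [treatment_table()] and
#'   [contrast_vs_control()] for downstream summaries.
#' @export
fit_flush <- function(data, weights = NULL, spec = nlme_spec()) {
  need <- c("bed_id", "block_id", "treatment", "tprime", "yprime")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("flush data is missing column(s): ", paste(missing, collapse = ", "))
  if (!is.null(data$flush) && length(unique(data$flush)) > 1)
    stop("fit_flush expects data from a single flush")
  if (all(data$yprime == 0))
    stop("degenerate flush: all transformed yields are zero")
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data), all(weights > 0))

  obs_per_bed <- table(data$bed_id)
  if (any(obs_per_bed < 5))
    warning("some beds have fewer than 5 observations in this flush")
  beds_per_trt <- table(unique(data[, c("bed_id", "treatment")])$treatment)
  if (any(beds_per_trt < 2))
    warning("fewer than 2 beds for some treatment(s); ",
            "estimates may be weakly identified")

  if (spec$estimator == "two_stage") fit_flush_two_stage(data, weights, spec)
  else fit_flush_saem(data, weights, spec)
}

# ---- starting values ---------------------------------------------------

# Data-driven initializer: A0 per treatment from the observed plateaus,
# C0/B0 from the linearising regression log(-log(y/A0)) = B - C t.
data_start <- function(data, fallback) {
  trts <- sort(unique(data$treatment))
  bed_max <- stats::aggregate(yprime ~ bed_id + treatment, data, max)
  A0 <- vapply(trts, function(tt)
    1.05 * mean(bed_max$yprime[bed_max$treatment == tt]), numeric(1))
  A0[A0 <= 0] <- fallback["A"]
  Aref <- unname(A0[data$treatment])
  frac <- data$yprime / Aref
  keep <- frac > 0.02 & frac < 0.98
  if (sum(keep) >= 3) {
    z <- log(-log(frac[keep]))
    sl <- stats::coef(stats::lm(z ~ data$tprime[keep]))
    C0 <- max(1e-3, -unname(sl[2]))
    B0 <- unname(sl[1])
    if (!is.finite(C0) || !is.finite(B0)) { C0 <- fallback["C"]; B0 <- fallback["B"] }
  } else {
    C0 <- fallback["C"]; B0 <- fallback["B"]
  }
  list(A = A0, B = stats::setNames(rep(B0, length(trts)), trts), C = C0)
}

config_start <- function(data, start) {
  trts <- sort(unique(data$treatment))
  list(A = stats::setNames(rep(unname(start["A"]), length(trts)), trts),
       B = stats::setNames(rep(unname(start["B"]), length(trts)), trts),
       C = unname(start["C"]))
}

# ---- SAEM engine -------------------------------------------------------

fit_flush_saem <- function(data, weights, spec) {
  ord <- order(data$bed_id, data$tprime)
  data <- data[ord, , drop = FALSE]
  weights <- weights[ord]
  beds <- unique(data[, c("bed_id", "block_id", "treatment")])
  beds <- beds[order(beds$bed_id), ]
  nbed <- nrow(beds)
  trts <- sort(unique(beds$treatment))
  ntrt <- length(trts)
  blocks <- sort(unique(beds$block_id))
  nblk <- length(blocks)
  use_block <- nblk >= 2
  block_on_B <- use_block && spec$block_effects == "AB"

  bedidx <- match(data$bed_id, beds$bed_id)
  blkidx <- match(beds$block_id, blocks)
  trtidx <- match(beds$treatment, trts)
  y <- data$yprime
  tt <- data$tprime
  w <- weights
  n <- length(y)
  n_t <- tabulate(trtidx, ntrt)  # beds per treatment

  st <- if (spec$start_values == "data") data_start(data, spec$start)
        else config_start(data, spec$start)
  A_t <- unname(st$A[trts]); B_t <- unname(st$B[trts]); C <- st$C

  with_seed(spec$seed, {
    # latent state
    phiA <- A_t[trtidx]
    phiB <- B_t[trtidx]
    aA <- rep(0, nblk); aB <- rep(0, nblk)

    scaleA <- max(mean(abs(A_t)), 1)
    v_bedA <- (0.15 * scaleA)^2
    v_bedB <- 0.15^2
    v_blkA <- if (use_block) (0.08 * scaleA)^2 else 0
    v_blkB <- if (block_on_B) 0.08^2 else 0
    fl_bedA <- (1e-4 * scaleA)^2; fl_bedB <- 1e-8
    fl_blkA <- fl_bedA; fl_blkB <- fl_bedB
    fl_res <- (1e-6 * scaleA)^2

    fcur <- phiA[bedidx] * exp(-exp(phiB[bedidx] - C * tt))
    v_res <- max(sum(w * (y - fcur)^2) / n, fl_res)

    sA <- rep(0.1 * scaleA, nbed)  # adaptive proposal scales
    sB <- rep(0.1, nbed)

    niter <- spec$n_burnin + spec$n_smooth
    p <- 2 * ntrt + 1
    trace <- matrix(NA_real_, niter, p,
                    dimnames = list(NULL, c(paste0("A_", trts),
                                            paste0("B_", trts), "C")))
    ll_trace <- numeric(niter)
    # smoothed sufficient statistics
    S_A1 <- rowsum_safe(phiA - aA[blkidx], trtidx, ntrt)
    S_B1 <- rowsum_safe(phiB - aB[blkidx], trtidx, ntrt)
    S_A2 <- rowsum_safe((phiA - aA[blkidx])^2, trtidx, ntrt)
    S_B2 <- rowsum_safe((phiB - aB[blkidx])^2, trtidx, ntrt)
    S_blkA <- sum(aA^2); S_blkB <- sum(aB^2)
    S_res <- sum(w * (y - fcur)^2)
    phiA_bar <- phiA; phiB_bar <- phiB
    aA_bar <- aA; aB_bar <- aB
    # Louis accumulators
    Hbar <- matrix(0, p, p); Pbar <- matrix(0, p, p); sbar <- numeric(p)
    acc_tot <- 0; acc_n <- 0

    for (m in seq_len(niter)) {
      burn <- m <= spec$n_burnin
      gam <- if (burn) 1 else 1 / (m - spec$n_burnin)

      for (pass in seq_len(spec$n_mh)) {
        # --- Metropolis update of per-bed asymptotes (A) -------------
        propA <- phiA + stats::rnorm(nbed, 0, sA)
        gcur <- exp(-exp(phiB[bedidx] - C * tt))  # A-free factor
        fprop <- propA[bedidx] * gcur
        d_rss <- rowsum_safe(w * ((y - fprop)^2 - (y - fcur)^2), bedidx, nbed)
        mA <- A_t[trtidx] + aA[blkidx]
        d_pr <- ((propA - mA)^2 - (phiA - mA)^2) / v_bedA
        logr <- -(d_rss / v_res + d_pr) / 2
        logr[propA <= 0] <- -Inf  # asymptotes must stay positive
        acc <- log(stats::runif(nbed)) < logr
        if (any(acc)) {
          phiA[acc] <- propA[acc]
          swap <- acc[bedidx]
          fcur[swap] <- fprop[swap]
        }
        if (burn) sA <- pmin(pmax(sA * exp(0.1 * (acc - 0.3)),
                                  1e-6 * scaleA), 2 * scaleA)
        acc_tot <- acc_tot + sum(acc); acc_n <- acc_n + nbed

        # --- Metropolis update of per-bed growth rates (B) -----------
        propB <- phiB + stats::rnorm(nbed, 0, sB)
        fprop <- phiA[bedidx] * exp(-exp(propB[bedidx] - C * tt))
        d_rss <- rowsum_safe(w * ((y - fprop)^2 - (y - fcur)^2), bedidx, nbed)
        mB <- B_t[trtidx] + aB[blkidx]
        d_pr <- ((propB - mB)^2 - (phiB - mB)^2) / v_bedB
        logr <- -(d_rss / v_res + d_pr) / 2
        acc <- log(stats::runif(nbed)) < logr
        if (any(acc)) {
          phiB[acc] <- propB[acc]
          swap <- acc[bedidx]
          fcur[swap] <- fprop[swap]
        }
        if (burn) sB <- pmin(pmax(sB * exp(0.1 * (acc - 0.3)), 1e-6), 2)
        acc_tot <- acc_tot + sum(acc); acc_n <- acc_n + nbed

        # --- Gibbs update of block effects ---------------------------
        if (use_block) {
          resA <- rowsum_safe(phiA - A_t[trtidx], blkidx, nblk)
          nb <- tabulate(blkidx, nblk)
          prec <- nb / v_bedA + 1 / max(v_blkA, fl_blkA)
          aA <- stats::rnorm(nblk, (resA / v_bedA) / prec, sqrt(1 / prec))
          # sum-to-zero identification: the split between the overall level
          # and the block effects is informed only by the prior, so with few
          # blocks the chain's block-effect mean can wander and drag every
          # treatment level with it. Recentre and transfer the mean into the
          # fixed effects; each bed's prior mean A_t + a_b is unchanged.
          mw <- mean(aA); aA <- aA - mw; A_t <- A_t + mw
          if (block_on_B) {
            resB <- rowsum_safe(phiB - B_t[trtidx], blkidx, nblk)
            precB <- nb / v_bedB + 1 / max(v_blkB, fl_blkB)
            aB <- stats::rnorm(nblk, (resB / v_bedB) / precB, sqrt(1 / precB))
            mw <- mean(aB); aB <- aB - mw; B_t <- B_t + mw
          }
        }
      }

      # --- M-step: shared C by 1-D minimisation, SA-damped -------------
      obj <- function(cc) sum(w * (y - phiA[bedidx] *
                                     exp(-exp(phiB[bedidx] - cc * tt)))^2)
      Cstar <- stats::optimize(obj, c(max(1e-4, C / 3), min(5, C * 3)))$minimum
      C <- C + gam * (Cstar - C)
      fcur <- phiA[bedidx] * exp(-exp(phiB[bedidx] - C * tt))

      # --- M-step: sufficient statistics -------------------------------
      dA <- phiA - aA[blkidx]; dB <- phiB - aB[blkidx]
      S_A1 <- S_A1 + gam * (rowsum_safe(dA, trtidx, ntrt) - S_A1)
      S_B1 <- S_B1 + gam * (rowsum_safe(dB, trtidx, ntrt) - S_B1)
      S_A2 <- S_A2 + gam * (rowsum_safe(dA^2, trtidx, ntrt) - S_A2)
      S_B2 <- S_B2 + gam * (rowsum_safe(dB^2, trtidx, ntrt) - S_B2)
      S_blkA <- S_blkA + gam * (sum(aA^2) - S_blkA)
      S_blkB <- S_blkB + gam * (sum(aB^2) - S_blkB)
      S_res <- S_res + gam * (sum(w * (y - fcur)^2) - S_res)

      A_t <- S_A1 / n_t
      B_t <- S_B1 / n_t
      # REML-style df correction: the ntrt treatment means absorb ntrt
      # degrees of freedom from the centred sum of squares; dividing by
      # nbed (plain ML) biases the bed variance low by (nbed-ntrt)/nbed
      # and with it every fixed-effect standard error.
      df_bed <- max(nbed - ntrt, 1)
      upd_bedA <- max(sum(S_A2 - S_A1^2 / n_t) / df_bed, fl_bedA)
      upd_bedB <- max(sum(S_B2 - S_B1^2 / n_t) / df_bed, fl_bedB)
      upd_res <- max(S_res / n, fl_res)
      if (burn) {  # simulated-annealing damping against premature collapse
        v_bedA <- max(upd_bedA, 0.98 * v_bedA)
        v_bedB <- max(upd_bedB, 0.98 * v_bedB)
        v_res <- max(upd_res, 0.98 * v_res)
      } else {
        v_bedA <- upd_bedA; v_bedB <- upd_bedB; v_res <- upd_res
      }
      if (use_block) {  # centred effects carry nblk - 1 degrees of freedom
        upd <- max(S_blkA / max(nblk - 1, 1), fl_blkA)
        v_blkA <- if (burn) max(upd, 0.98 * v_blkA) else upd
      }
      if (block_on_B) {
        upd <- max(S_blkB / max(nblk - 1, 1), fl_blkB)
        v_blkB <- if (burn) max(upd, 0.98 * v_blkB) else upd
      }

      # conditional means of the latent effects (smoothing phase)
      if (!burn) {
        phiA_bar <- phiA_bar + gam * (phiA - phiA_bar)
        phiB_bar <- phiB_bar + gam * (phiB - phiB_bar)
        aA_bar <- aA_bar + gam * (aA - aA_bar)
        aB_bar <- aB_bar + gam * (aB - aB_bar)
        louis <- louis_terms(y, tt, w, phiA, phiB, aA, aB, bedidx, blkidx,
                             trtidx, A_t, B_t, C, v_bedA, v_bedB, v_res,
                             n_t, ntrt)
        Hbar <- Hbar + gam * (louis$negH - Hbar)
        Pbar <- Pbar + gam * (tcrossprod(louis$score) - Pbar)
        sbar <- sbar + gam * (louis$score - sbar)
      }

      trace[m, ] <- c(A_t, B_t, C)
      ll_trace[m] <- -0.5 * (n * log(2 * pi * v_res) - sum(log(w)) +
                               sum(w * (y - fcur)^2) / v_res)
    }

    # ---- convergence: normalised trend of the fixed-effect traces ----
    win <- min(spec$convergence_window, spec$n_smooth)
    rows <- (niter - win + 1):niter
    it <- seq_along(rows)
    slopes <- apply(trace[rows, , drop = FALSE], 2, function(th)
      stats::cov(it, th) / stats::var(it))
    norm_slope <- abs(slopes) / (abs(trace[niter, ]) + 1e-8)
    converged <- all(norm_slope < spec$convergence_tol)
    if (!converged)
      stop(errorCondition(
        paste0("SAEM did not stabilise: max normalised trace slope ",
               format(max(norm_slope), digits = 3), " over the final ",
               win, " iterations exceeds ", spec$convergence_tol),
        trace = trace, loglik_trace = ll_trace,
        class = c("flushcurve_convergence_error", "error", "condition")))

    info <- Hbar - Pbar + tcrossprod(sbar)
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(vc) || any(diag(vc) <= 0)) {
      # fall back to the complete-data information (conservative block-diagonal)
      vc <- tryCatch(solve(Hbar), error = function(e) {
        diag(1 / pmax(diag(Hbar), 1e-12))
      })
    }
    dimnames(vc) <- list(colnames(trace), colnames(trace))
    se <- sqrt(pmax(diag(vc), 0))

    fit_ind <- phiA_bar[bedidx] * exp(-exp(phiB_bar[bedidx] - C * tt))
    fit_pop <- A_t[trtidx[bedidx]] * exp(-exp(B_t[trtidx[bedidx]] - C * tt))

    est <- rbind(
      data.frame(parameter = "A", treatment = trts, estimate = A_t,
                 se = se[seq_len(ntrt)]),
      data.frame(parameter = "B", treatment = trts, estimate = B_t,
                 se = se[ntrt + seq_len(ntrt)]),
      data.frame(parameter = "C", treatment = NA_character_, estimate = C,
                 se = se[p])
    )
    rownames(est) <- NULL

    structure(list(
      estimates = est,
      vcov = vc,
      var_components = c(bed_A = v_bedA, bed_B = v_bedB,
                         block_A = if (use_block) v_blkA else NA_real_,
                         block_B = if (block_on_B) v_blkB else NA_real_,
                         residual = v_res),
      random_effects = list(
        bed = data.frame(beds, phi_A = phiA_bar, phi_B = phiB_bar),
        block = data.frame(block_id = blocks, a_A = aA_bar, a_B = aB_bar)),
      fitted = data.frame(bed_id = data$bed_id, treatment = data$treatment,
                          tprime = tt, yprime = y, weight = w,
                          fitted = fit_ind, fitted_population = fit_pop),
      r2 = efron_r2(y, fit_ind),
      r2_population = efron_r2(y, fit_pop),
      converged = converged,
      trace = trace,
      loglik_trace = ll_trace,
      acceptance_rate = acc_tot / acc_n,
      estimator = "saem",
      treatments = trts,
      spec = spec,
      n_obs = n,
      weighted = !all(w == 1)
    ), class = "gompertz_fit")
  })
}

# rowsum() that keeps empty groups and returns a plain vector
rowsum_safe <- function(x, g, ng) {
  out <- numeric(ng)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Complete-data score and (negative) Hessian of the fixed effects
# (A per treatment, B per treatment, shared C) for Louis' identity.
louis_terms <- function(y, tt, w, phiA, phiB, aA, aB, bedidx, blkidx, trtidx,
                        A_t, B_t, C, v_bedA, v_bedB, v_res, n_t, ntrt) {
  p <- 2 * ntrt + 1
  score <- numeric(p)
  negH <- matrix(0, p, p)
  dA <- (phiA - A_t[trtidx] - aA[blkidx]) / v_bedA
  dB <- (phiB - B_t[trtidx] - aB[blkidx]) / v_bedB
  score[seq_len(ntrt)] <- rowsum_safe(dA, trtidx, ntrt)
  score[ntrt + seq_len(ntrt)] <- rowsum_safe(dB, trtidx, ntrt)
  u <- phiB[bedidx] - C * tt
  f <- phiA[bedidx] * exp(-exp(u))
  dfdC <- phiA[bedidx] * exp(u - exp(u)) * tt
  d2fdC2 <- phiA[bedidx] * tt^2 * exp(u - exp(u)) * (exp(u) - 1)
  r <- y - f
  score[p] <- sum(w * r * dfdC) / v_res
  diag(negH)[seq_len(ntrt)] <- n_t / v_bedA
  diag(negH)[ntrt + seq_len(ntrt)] <- n_t / v_bedB
  negH[p, p] <- sum(w * (dfdC^2 - r * d2fdC2)) / v_res
  list(score = score, negH = negH)
}
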