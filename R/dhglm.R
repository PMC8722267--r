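# Double hierarchical generalized linear model for litter-size variability.
#
# The mean part models TNB with additive + permanent-environment random
# effects; the variance part models the log residual variance with the same
# factor structure, through the gamma-GLM working response
#   psi_work = psi_hat + (e^2 / (1 - h) - exp(psi_hat)) / exp(psi_hat)
# (e = mean-part residual, h = its hat-diagonal leverage, psi_hat = current
# variance-part linear predictor; the first cycle starts from
# log(e^2 / (1 - h))). The two parts are coupled through unstructured 2x2
# additive and permanent-environment covariance matrices and through the
# iteratively reweighted residuals:
#   W  = diag(exp(psi_hat))^-1      (mean part)
#   W_v = diag((1 - h) / 2)         (variance part)
# with scaling variances sigma2_e, sigma2_ev expected to be ~1. The
# linearised working response (rather than the raw log of squared
# residuals) is what makes the scaling variances converge to ~1: the raw
# log response is offset by the mean of log chi-square(1) and would push
# the mean-part scaling variance to ~exp(1.27).

PSI_EPS <- 1e-12
PSI_QMAX <- 36      # trim of the standardized squared residual (6 sigma)
PSI_HAT_MIN <- -10  # bounds of the variance-part linear predictor
PSI_HAT_MAX <- 15

# gamma-GLM working response for the variance part, evaluated at the
# current linear predictor psi_hat: first-order expansion of
# log(e^2/(1-h)) around exp(psi_hat), with the standardized squared
# residual trimmed for numerical robustness
dhglm_work_response <- function(psi_hat, e, h) {
  q <- pmax(e^2, PSI_EPS) / ((1 - h) * exp(psi_hat))
  psi_hat + pmin(q, PSI_QMAX) - 1
}

# precompute stacked designs shared by all DHGLM iterations
dhglm_system <- function(records, ped) {
  n <- nrow(records)
  labels <- attr(ped, "labels")
  aidx <- match(as.character(records$sow), labels)
  if (anyNA(aidx)) stop("sow id not present in pedigree", call. = FALSE)
  nA <- nrow(ped)
  X1 <- mm_fixed_design(records, c("hys", "parity"), n)
  p1 <- ncol(X1)
  X <- rbind(cbind(X1, matrix(0, n, p1)), cbind(matrix(0, n, p1), X1))
  colnames(X) <- c(colnames(X1), paste0("v_", colnames(X1)))
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1, dims = c(n, nA))
  Zb <- Matrix::bdiag(Za, Za)
  fs <- factor(records$sow)
  ns <- nlevels(fs)
  Zpe <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fs), x = 1,
                              dims = c(n, ns))
  Zpeb <- Matrix::bdiag(Zpe, Zpe)
  Ainv <- build_a_inverse(ped)
  terms <- list(mm_term("animal", Zb, Kinv = Ainv, struct = "us2"),
                mm_term("pe", Zpeb, struct = "us2"))
  list(y = records$tnb, X = X, terms = terms, n = n, nA = nA,
       labels = labels, sow_levels = levels(fs), aidx = aidx)
}

#' Initialize the DHGLM iteration
#'
#' Builds the starting state from a converged mean-model fit. The
#' variance-part linear predictor starts flat at `log(sigma2_e)`, so the
#' initial working response is
#' `psi = log(sigma2_e) + e^2 / ((1 - h) sigma2_e) - 1`
#' (the gamma linearisation of `log(e^2/(1-h))` at the homoscedastic
#' residual variance). Mean-part weights start at `1 / sigma2_e`,
#' variance-part weights at `(1 - h) / 2`; the covariance matrices are
#' seeded with the mean-fit additive and permanent-environment variances
#' and small positive variance-part variances (zero cross covariances).
#'
#' @param mean_fit an [fit_animal_model()] result with residuals and
#'   leverages.
#' @return a `lv_dhglm_state` list.
#' @export
initialize_dhglm <- function(mean_fit) {
  stopifnot(inherits(mean_fit, "lv_mm_fit"))
  e <- mean_fit$residuals
  h <- mean_fit$leverage
  if (is.null(h)) stop("mean fit must carry leverages", call. = FALSE)
  h <- pmin(pmax(h, 0), 1 - 1e-8)
  s2e <- mean_fit$vc$var_e[1]
  psi_hat0 <- rep(log(s2e), length(e))
  psi <- dhglm_work_response(psi_hat0, e, h)
  Ga <- diag(c(max(mean_fit$vc$var_a, 1e-4), 0.01))
  Gpe <- diag(c(max(mean_fit$vc$var_pe, 1e-4), 0.01))
  structure(list(
    iter = 0L, psi = psi, psi_hat = psi_hat0, h = h,
    W = rep(1 / s2e, length(e)), Wv = (1 - h) / 2,
    Ga = Ga, Gpe = Gpe, s2e = 1, s2ev = 1,
    fit = NULL, trace = list()
  ), class = "lv_dhglm_state")
}

dhglm_vc_vec <- function(state) {
  c(ga11 = state$Ga[1, 1], ga12 = state$Ga[1, 2], ga22 = state$Ga[2, 2],
    gp11 = state$Gpe[1, 1], gp12 = state$Gpe[1, 2], gp22 = state$Gpe[2, 2],
    s2e = state$s2e, s2ev = state$s2ev)
}

#' One DHGLM update cycle
#'
#' Fits the stacked bivariate system at the current weights and working
#' response, re-estimates the 2x2 covariance matrices and scaling variances
#' by REML (warm-started, iteration-capped), then refreshes the working
#' response `psi = log(e^2/(1-h))`, the mean-part weights `exp(-psi_hat)`
#' and the variance-part weights `(1-h)/2`.
#'
#' @param state a `lv_dhglm_state`.
#' @param sys the precomputed system from `dhglm_system()` (internal; built
#'   by [run_dhglm()]).
#' @param reml_maxit inner REML iteration cap for this cycle.
#' @param se compute the REML information matrix on this cycle (used on the
#'   final cycle only).
#' @param damp relaxation factor in `[0, 1)` mixing the previous
#'   variance-part linear predictor into the new one.
#' @return updated `lv_dhglm_state`.
#' @export
dhglm_update <- function(state, sys, reml_maxit = 10L, se = FALSE,
                         damp = 0) {
  stopifnot(inherits(state, "lv_dhglm_state"))
  n <- sys$n
  ystar <- c(sys$y, state$psi)
  rgroup <- rep(1:2, each = n)
  rweights <- c(state$W, state$Wv)
  if (max(abs(state$psi)) > 100) {
    stop("DHGLM diverged: working response exceeded 100 in magnitude",
         call. = FALSE)
  }
  eng <- mm_engine(
    ystar, sys$X, sys$terms, rgroup = rgroup, rweights = rweights,
    start = list(term_vc = list(state$Ga, state$Gpe),
                 resid_vc = c(state$s2e, state$s2ev)),
    reml = TRUE, maxit = reml_maxit, se = se,
    compute_leverage = TRUE, leverage_rows = seq_len(n),
    compute_pev = FALSE, on_nonconv = "ignore")
  e <- eng$residuals[seq_len(n)]
  state2 <- state
  state2$iter <- state$iter + 1L
  state2$Ga <- eng$vc$term_vc[[1]]
  state2$Gpe <- eng$vc$term_vc[[2]]
  state2$s2e <- eng$vc$resid_vc[1]
  state2$s2ev <- eng$vc$resid_vc[2]
  state2$fit <- eng
  # hat leverages of the mean-part rows of the fitted stacked system
  h <- pmin(pmax(eng$leverage[seq_len(n)], 0), 1 - 1e-8)
  state2$h <- h
  psi_hat <- eng$fitted[n + seq_len(n)]
  psi_hat <- pmin(pmax(psi_hat, PSI_HAT_MIN), PSI_HAT_MAX)
  if (damp > 0 && !is.null(state$psi_hat)) {
    psi_hat <- damp * state$psi_hat + (1 - damp) * psi_hat
  }
  state2$psi <- dhglm_work_response(psi_hat, e, h)
  state2$psi_hat <- psi_hat
  state2$W <- exp(-psi_hat)
  state2$Wv <- (1 - h) / 2
  state2$trace <- c(state$trace, list(dhglm_vc_vec(state2)))
  state2
}

#' Fit the DHGLM for litter-size variability
#'
#' Iterates [dhglm_update()] from [initialize_dhglm()] until the relative
#' change of every variance component falls below `tol` and successive
#' variance-part EBV correlate above `1 - cor_tol`, or until `max_iter`.
#'
#' @param records edited litter record table (`sow`, `parity`, `hys`, `tnb`).
#' @param ped pedigree covering all sows.
#' @param tol relative variance-component convergence tolerance.
#' @param cor_tol EBV-stability tolerance (`cor > 1 - cor_tol`).
#' @param max_iter outer iteration cap.
#' @param reml_maxit inner REML iteration cap for the first cycle.
#' @param reml_maxit_later inner REML cap for the warm-started later cycles.
#' @param damp relaxation factor in (0, 1) applied to the variance-part
#'   linear predictor from the fourth cycle on (0 = no damping); stabilises
#'   the weight/response feedback.
#' @param se compute standard errors of components and correlations at
#'   convergence (adds one numerical-information pass).
#' @param start_mean optional starting values for the initial mean fit.
#' @param on_nonconv "warn" (default) or "error" when `max_iter` is hit.
#' @return `lv_dhglm_result`: list with `Ga`, `Gpe`, scaling variances
#'   `s2e`/`s2ev`, correlations `r_a_av`, `r_pe_pev` (with SEs if requested),
#'   `ebv` (per-animal mean/variance EBV and PEV), `psi_hat` (per-record
#'   predicted log residual variance), `trace`, `iterations`, `converged`.
#' @export
run_dhglm <- function(records, ped, tol = 5e-3, cor_tol = 1e-6,
                      max_iter = 25L, reml_maxit = 30L,
                      reml_maxit_later = 10L, damp = 0.5, se = FALSE,
                      start_mean = NULL, on_nonconv = "warn") {
  sys <- dhglm_system(records, ped)
  mean_fit <- fit_animal_model(records, "tnb", fixed = c("hys", "parity"),
                               ped = ped, animal = "sow",
                               permanent_env = "sow", start = start_mean,
                               reml = TRUE, compute_pev = FALSE,
                               compute_leverage = TRUE)
  state <- initialize_dhglm(mean_fit)
  converged <- FALSE
  prev_av <- NULL
  for (it in seq_len(max_iter)) {
    vc_old <- dhglm_vc_vec(state)
    state <- dhglm_update(state, sys,
                          reml_maxit = if (it == 1L) reml_maxit
                          else reml_maxit_later,
                          damp = if (it > 3L) damp else 0)
    vc_new <- dhglm_vc_vec(state)
    rel <- abs(vc_new - vc_old) / pmax(abs(vc_old), 1e-8)
    av <- state$fit$u[["animal"]][sys$nA + seq_len(sys$nA)]
    cor_ok <- if (is.null(prev_av)) FALSE else {
      stats::cor(av, prev_av) > 1 - cor_tol
    }
    prev_av <- av
    if (max(rel) < tol && cor_ok) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    msg <- sprintf("DHGLM did not converge in %d iterations", max_iter)
    if (identical(on_nonconv, "error")) {
      stop(structure(class = c("lv_nonconvergence", "error", "condition"),
                     list(message = msg, call = sys.call())))
    }
    warning(msg, call. = FALSE)
  }
  # final pass: PEV (and optionally SEs) at the converged weights
  n <- sys$n
  eng <- mm_engine(
    c(sys$y, state$psi), sys$X, sys$terms,
    rgroup = rep(1:2, each = n), rweights = c(state$W, state$Wv),
    start = list(term_vc = list(state$Ga, state$Gpe),
                 resid_vc = c(state$s2e, state$s2ev)),
    reml = FALSE, se = FALSE, compute_leverage = FALSE, compute_pev = TRUE)
  if (se) {
    ctxpar <- list(term_vc = list(state$Ga, state$Gpe),
                   resid_vc = c(state$s2e, state$s2ev))
    eng_se <- mm_engine(
      c(sys$y, state$psi), sys$X, sys$terms,
      rgroup = rep(1:2, each = n), rweights = c(state$W, state$Wv),
      start = ctxpar, reml = TRUE, maxit = 3L, se = TRUE,
      compute_leverage = FALSE, compute_pev = FALSE, on_nonconv = "ignore")
  }
  Ga <- state$Ga; Gpe <- state$Gpe
  r_a_av <- Ga[1, 2] / sqrt(Ga[1, 1] * Ga[2, 2])
  r_pe_pev <- Gpe[1, 2] / sqrt(Gpe[1, 1] * Gpe[2, 2])
  se_out <- NULL
  if (se) {
    corfun <- function(which_term) function(pp) {
      vc <- mm_par_unpack(pp, sys$terms, 2L)
      G <- vc$term_vc[[which_term]]
      G[1, 2] / sqrt(G[1, 1] * G[2, 2])
    }
    vfun <- function(k) function(pp) {
      vc <- mm_par_unpack(pp, sys$terms, 2L)
      c(vc$term_vc[[1]][1, 1], vc$term_vc[[1]][2, 2],
        vc$term_vc[[2]][1, 1], vc$term_vc[[2]][2, 2])[k]
    }
    se_out <- list(
      r_a_av = mm_fun_se(eng_se, corfun(1L)),
      r_pe_pev = mm_fun_se(eng_se, corfun(2L)),
      var_a = mm_fun_se(eng_se, vfun(1L)),
      var_av = mm_fun_se(eng_se, vfun(2L)),
      var_pe = mm_fun_se(eng_se, vfun(3L)),
      var_pev = mm_fun_se(eng_se, vfun(4L))
    )
  }
  ua <- eng$u[["animal"]]
  pev <- eng$pev[["animal"]]
  nA <- sys$nA
  ebv <- data.frame(
    animal = sys$labels,
    ebv_mean = ua[seq_len(nA)],
    ebv_var = ua[nA + seq_len(nA)],
    pev_mean = pev[seq_len(nA)],
    pev_var = pev[nA + seq_len(nA)],
    stringsAsFactors = FALSE
  )
  structure(list(
    Ga = Ga, Gpe = Gpe, s2e = state$s2e, s2ev = state$s2ev,
    r_a_av = r_a_av, r_pe_pev = r_pe_pev, se = se_out,
    ebv = ebv, psi_hat = state$psi_hat, leverage = state$h,
    psi_work = state$psi, W = state$W, Wv = state$Wv,
    trace = state$trace, iterations = state$iter, converged = converged,
    mean_fit_vc = mean_fit$vc
  ), class = "lv_dhglm_result")
}

#' @export
print.lv_dhglm_result <- function(x, ...) {
  cat("DHGLM fit (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("  additive:  var_a =", signif(x$Ga[1, 1], 4),
      " var_av =", signif(x$Ga[2, 2], 4),
      " r =", signif(x$r_a_av, 3), "\n")
  cat("  perm env:  var_pe =", signif(x$Gpe[1, 1], 4),
      " var_pev =", signif(x$Gpe[2, 2], 4),
      " r =", signif(x$r_pe_pev, 3), "\n")
  cat("  scaling variances:", signif(x$s2e, 4), signif(x$s2ev, 4), "\n")
  invisible(x)
}

#' Genetic coefficient of variation of the residual standard deviation
#'
#' Approximated as one half of the genetic standard deviation of the log
#' residual variance: `0.5 * sqrt(sigma2)`, where `sigma2` is the additive
#' variance of the variability phenotype (LnVarTNB or the DHGLM variance
#' part).
#'
#' @param sigma2_var_part additive variance of the variance part (>= 0).
#' @return the GCV on the SD level (unitless ratio; multiply by 100 for %).
#' @export
gcv_sde <- function(sigma2_var_part) {
  if (any(sigma2_var_part < 0)) stop("variance must be >= 0", call. = FALSE)
  0.5 * sqrt(sigma2_var_part)
}
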