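# Sparse mixed-model engine: Henderson's MME, REML by direct maximisation of
# the restricted log-likelihood (log / log-Cholesky parametrisation), BLUP
# solutions, prediction error variances and hat-diagonal leverages.
#
# Random-term covariance structures:
#   "var1" : u ~ N(0, K sigma2), K given through its sparse inverse (or I)
#   "us2"  : bivariate effects u = (u1', u2')' ~ N(0, G (x) K), G unstructured
#            2x2, parametrised by its Cholesky factor

mm_term <- function(label, Z, Kinv = NULL, struct = c("var1", "us2")) {
  struct <- match.arg(struct)
  Z <- methods::as(Z, "CsparseMatrix")
  ntrait <- if (struct == "us2") 2L else 1L
  nlev <- ncol(Z) / ntrait
  stopifnot(nlev == round(nlev))
  ldet_kinv <- 0
  if (!is.null(Kinv)) {
    Kinv <- Matrix::forceSymmetric(methods::as(Kinv, "CsparseMatrix"))
    stopifnot(nrow(Kinv) == nlev)
    ldet_kinv <- as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)
  }
  list(label = label, Z = Z, Kinv = Kinv, struct = struct,
       nlev = as.integer(nlev), ntrait = ntrait, ldet_kinv = ldet_kinv)
}

# --- parameter transforms ----------------------------------------------------

mm_par_pack <- function(term_vc, resid_vc) {
  par <- numeric(0)
  for (v in term_vc) {
    if (is.matrix(v)) {
      L <- t(chol(v))
      par <- c(par, log(L[1, 1]), L[2, 1], log(L[2, 2]))
    } else {
      par <- c(par, log(v))
    }
  }
  c(par, log(resid_vc))
}

mm_par_unpack <- function(par, terms, ngroups) {
  term_vc <- vector("list", length(terms))
  k <- 0L
  for (t in seq_along(terms)) {
    if (terms[[t]]$struct == "us2") {
      L <- matrix(c(exp(par[k + 1L]), par[k + 2L], 0, exp(par[k + 3L])), 2, 2)
      term_vc[[t]] <- L %*% t(L)
      k <- k + 3L
    } else {
      term_vc[[t]] <- exp(par[k + 1L])
      k <- k + 1L
    }
  }
  list(term_vc = term_vc, resid_vc = exp(par[k + seq_len(ngroups)]))
}

# --- core: -2 * restricted log-likelihood (up to an additive constant) -------

# Precompute everything that does not depend on the variance parameters:
# per-residual-group cross-products of the design, right-hand sides, and
# sparse "precision templates" that enter the coefficient matrix scaled by
# entries of the (inverse) term covariances. A symbolic Cholesky
# factorisation is cached across evaluations.
mm_build_ctx <- function(y, X, terms, rgroup, rweights) {
  n <- length(y)
  p <- ncol(X)
  Wmat <- methods::as(
    cbind(methods::as(X, "CsparseMatrix"),
          do.call(cbind, lapply(terms, `[[`, "Z"))), "CsparseMatrix")
  dimc <- ncol(Wmat)
  ngroups <- max(rgroup)
  Cg <- rg <- yy <- sumlogw <- ng <- vector("list", ngroups)
  for (g in seq_len(ngroups)) {
    sel <- which(rgroup == g)
    Wg <- Wmat[sel, , drop = FALSE]
    w <- rweights[sel]
    Cg[[g]] <- Matrix::forceSymmetric(
      Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% Wg))
    rg[[g]] <- Matrix::crossprod(Wg, w * y[sel])
    yy[[g]] <- sum(w * y[sel]^2)
    sumlogw[[g]] <- sum(log(w))
    ng[[g]] <- length(sel)
  }
  # precision templates: sparse Kinv (or identity) blocks padded to the
  # full coefficient-matrix dimension
  pad <- function(K, roff, coff) {
    # general storage first: symmetric classes keep only one triangle
    tri <- methods::as(methods::as(methods::as(
      K, "CsparseMatrix"), "generalMatrix"), "TsparseMatrix")
    Matrix::sparseMatrix(i = tri@i + 1L + roff, j = tri@j + 1L + coff,
                         x = tri@x, dims = c(dimc, dimc))
  }
  templ <- vector("list", length(terms))
  offs <- p
  for (t in seq_along(terms)) {
    tm <- terms[[t]]
    K <- if (is.null(tm$Kinv)) Matrix::Diagonal(tm$nlev) else tm$Kinv
    if (tm$struct == "us2") {
      o1 <- offs; o2 <- offs + tm$nlev
      T12 <- pad(K, o1, o2)
      templ[[t]] <- list(T11 = pad(K, o1, o1),
                         T12s = Matrix::forceSymmetric(T12 + Matrix::t(T12)),
                         T22 = pad(K, o2, o2))
    } else {
      templ[[t]] <- list(T11 = pad(K, offs, offs))
    }
    offs <- offs + ncol(tm$Z)
  }
  env <- new.env(parent = emptyenv())
  env$y <- y; env$Wmat <- Wmat; env$terms <- terms
  env$rgroup <- rgroup; env$rweights <- rweights
  env$ngroups <- ngroups; env$p <- p; env$dimc <- dimc
  env$Cg <- Cg; env$rg <- rg; env$yy <- unlist(yy)
  env$sumlogw <- unlist(sumlogw); env$ng <- unlist(ng)
  env$templ <- templ
  env$chol_cache <- NULL
  env
}

mm_m2ll <- function(par, ctx, want_fit = FALSE) {
  vc <- mm_par_unpack(par, ctx$terms, ctx$ngroups)
  s2g <- vc$resid_vc
  C <- ctx$Cg[[1]] / s2g[1]
  if (ctx$ngroups > 1) {
    for (g in 2:ctx$ngroups) C <- C + ctx$Cg[[g]] / s2g[g]
  }
  ld_G <- 0
  for (t in seq_along(ctx$terms)) {
    tm <- ctx$terms[[t]]
    v <- vc$term_vc[[t]]
    tp <- ctx$templ[[t]]
    if (tm$struct == "us2") {
      det_v <- v[1, 1] * v[2, 2] - v[1, 2]^2
      if (!is.finite(det_v) || det_v <= 0) {
        return(if (want_fit) NULL else 1e10)
      }
      Gi <- matrix(c(v[2, 2], -v[1, 2], -v[1, 2], v[1, 1]), 2) / det_v
      # an exactly-zero coefficient would drop the off-diagonal blocks from
      # the sparsity pattern and invalidate the cached symbolic Cholesky
      g12 <- if (Gi[1, 2] == 0) 1e-300 else Gi[1, 2]
      C <- C + Gi[1, 1] * tp$T11 + g12 * tp$T12s + Gi[2, 2] * tp$T22
      ld_G <- ld_G + tm$nlev * log(det_v) - 2 * tm$ldet_kinv
    } else {
      C <- C + tp$T11 / v
      ld_G <- ld_G + tm$nlev * log(v) - tm$ldet_kinv
    }
  }
  C <- Matrix::forceSymmetric(C)
  Ch <- NULL
  if (!is.null(ctx$chol_cache)) {
    Ch <- tryCatch(stats::update(ctx$chol_cache, C),
                   error = function(e) NULL)
  }
  if (is.null(Ch)) {
    Ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE),
                   error = function(e) NULL)
    if (!is.null(Ch)) ctx$chol_cache <- Ch
  }
  if (is.null(Ch)) return(if (want_fit) NULL else 1e10)
  rhs <- ctx$rg[[1]] / s2g[1]
  if (ctx$ngroups > 1) {
    for (g in 2:ctx$ngroups) rhs <- rhs + ctx$rg[[g]] / s2g[g]
  }
  sol <- tryCatch(Matrix::solve(Ch, rhs), error = function(e) NULL)
  if (is.null(sol)) return(if (want_fit) NULL else 1e10)
  ld_C <- as.numeric(Matrix::determinant(Ch, logarithm = TRUE,
                                         sqrt = FALSE)$modulus)
  ld_R <- sum(ctx$ng * log(s2g)) - sum(ctx$sumlogw)
  quad <- sum(ctx$yy / s2g) - sum(sol * rhs)
  val <- ld_R + ld_G + ld_C + quad
  if (!is.finite(val)) return(if (want_fit) NULL else 1e10)
  if (!want_fit) return(val)
  rinv <- ctx$rweights / s2g[ctx$rgroup]
  list(m2ll = val, vc = vc, sol = as.numeric(sol), Ch = Ch, rinv = rinv)
}

# quadratic forms m_i' C^{-1} m_i for every row of Wmat, in chunks
mm_row_quad <- function(Ch, Wmat, rows = seq_len(nrow(Wmat)), chunk = 1500L) {
  out <- numeric(length(rows))
  Wt <- Matrix::t(Wmat)
  for (st in seq(1L, length(rows), by = chunk)) {
    en <- min(st + chunk - 1L, length(rows))
    B <- Wt[, rows[st:en], drop = FALSE]
    S <- Matrix::solve(Ch, B)
    out[st:en] <- Matrix::colSums(B * S)
  }
  out
}

# diagonal of C^{-1} at the given global indices, in chunks
mm_diag_cinv <- function(Ch, dim_c, idx, chunk = 1500L) {
  out <- numeric(length(idx))
  for (st in seq(1L, length(idx), by = chunk)) {
    en <- min(st + chunk - 1L, length(idx))
    cols <- idx[st:en]
    B <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                              dims = c(dim_c, length(cols)))
    S <- Matrix::solve(Ch, B)
    out[st:en] <- Matrix::colSums(B * S)
  }
  out
}

# --- engine ------------------------------------------------------------------

#' @keywords internal
mm_engine <- function(y, X, terms, rgroup = NULL, rweights = NULL,
                      start, reml = TRUE, maxit = 200L,
                      se = FALSE, compute_leverage = TRUE,
                      leverage_rows = NULL,
                      compute_pev = TRUE, on_nonconv = "warn") {
  n <- length(y)
  X <- as.matrix(X)
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (is.null(rgroup)) rgroup <- rep(1L, n)
  rgroup <- as.integer(factor(rgroup))
  ngroups <- max(rgroup)
  if (is.null(rweights)) rweights <- rep(1, n)
  stopifnot(all(rweights > 0), length(rweights) == n)
  ctx <- mm_build_ctx(y, X, terms, rgroup, rweights)
  Wmat <- ctx$Wmat
  par0 <- mm_par_pack(start$term_vc, start$resid_vc)
  # bounds: log-scale entries kept in [-12, 12]; free Cholesky off-diagonals
  # in [-30, 30]
  is_log <- unlist(c(lapply(terms, function(t)
    if (t$struct == "us2") c(TRUE, FALSE, TRUE) else TRUE),
    rep(TRUE, ngroups)))
  lower <- ifelse(is_log, -12, -30)
  upper <- ifelse(is_log, 12, 30)
  opt <- NULL
  if (reml && length(par0) > 0) {
    # forward-difference gradient reusing the objective value at the
    # current point (optim's internal numerical gradient would use two
    # evaluations per coordinate)
    last <- new.env(parent = emptyenv())
    fn <- function(p) {
      v <- mm_m2ll(p, ctx)
      last$par <- p; last$val <- v
      v
    }
    gr <- function(p) {
      f0 <- if (!is.null(last$par) && identical(last$par, p))
        last$val else mm_m2ll(p, ctx)
      h <- 1e-5
      vapply(seq_along(p), function(j) {
        pj <- p; pj[j] <- pj[j] + h
        (mm_m2ll(pj, ctx) - f0) / h
      }, numeric(1))
    }
    opt <- stats::optim(pmin(pmax(par0, lower), upper), fn, gr,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = maxit, factr = 1e7))
    par <- opt$par
    if (opt$convergence != 0 && maxit >= 100L) {
      msg <- sprintf("REML did not converge (code %d): %s",
                     opt$convergence, opt$message)
      if (identical(on_nonconv, "error")) {
        cond <- structure(class = c("lv_nonconvergence", "error", "condition"),
                          list(message = msg, call = sys.call()))
        stop(cond)
      }
      if (identical(on_nonconv, "warn")) warning(msg, call. = FALSE)
    }
  } else {
    par <- par0
  }
  fit <- mm_m2ll(par, ctx, want_fit = TRUE)
  if (is.null(fit)) stop("mixed model system is singular at the final parameter values",
                         call. = FALSE)
  sol <- fit$sol
  beta <- sol[seq_len(p)]
  names(beta) <- colnames(X)
  offs <- p
  u <- vector("list", length(terms))
  names(u) <- vapply(terms, `[[`, "", "label")
  idx_term <- vector("list", length(terms))
  for (t in seq_along(terms)) {
    qt <- ncol(terms[[t]]$Z)
    idx_term[[t]] <- offs + seq_len(qt)
    u[[t]] <- sol[idx_term[[t]]]
    offs <- offs + qt
  }
  fitted <- as.numeric(Wmat %*% sol)
  resid <- y - fitted
  lev <- NULL
  if (compute_leverage) {
    rows <- if (is.null(leverage_rows)) seq_len(n) else leverage_rows
    lev <- rep(NA_real_, n)
    lev[rows] <- fit$rinv[rows] * mm_row_quad(fit$Ch, Wmat, rows = rows)
  }
  pev <- NULL
  if (compute_pev) {
    pev <- vector("list", length(terms))
    names(pev) <- names(u)
    for (t in seq_along(terms)) {
      pev[[t]] <- mm_diag_cinv(fit$Ch, ncol(Wmat), idx_term[[t]])
    }
  }
  se_out <- NULL
  if (se && reml) {
    H <- tryCatch(stats::optimHess(par, function(pp) 0.5 * mm_m2ll(pp, ctx)),
                  error = function(e) NULL)
    Vpar <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    se_out <- list(par = par, vcov_par = Vpar)
  }
  structure(list(
    vc = fit$vc, beta = beta, u = u, fitted = fitted, residuals = resid,
    leverage = lev, pev = pev, m2ll = fit$m2ll, loglik = -0.5 * fit$m2ll,
    aliased = aliased, par = par, opt = opt, se_info = se_out,
    rgroup = rgroup, rweights = rweights,
    converged = is.null(opt) || opt$convergence == 0
  ), class = "lv_mm_engine")
}

# delta-method SE for smooth scalar functions of the transformed parameters
mm_fun_se <- function(engine_fit, fun, eps = 1e-4) {
  si <- engine_fit$se_info
  if (is.null(si) || is.null(si$vcov_par)) return(NA_real_)
  par <- si$par
  g <- vapply(seq_along(par), function(j) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + eps; pm[j] <- pm[j] - eps
    (fun(pp) - fun(pm)) / (2 * eps)
  }, numeric(1))
  v <- as.numeric(t(g) %*% si$vcov_par %*% g)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

# --- public animal-model interface -------------------------------------------

#' Fit a pedigree animal model by REML
#'
#' Fits a Gaussian mixed model with herd-year-season/parity type fixed
#' factors, an additive genetic effect with pedigree covariance
#' (`a ~ N(0, A sigma2_a)`), an optional permanent-environment effect
#' (`pe ~ N(0, I sigma2_pe)`) for repeated records, and a residual that is
#' homogeneous, grouped (one variance per group), and/or weighted per record.
#' Variance components are estimated by direct REML maximisation on the
#' log scale; solutions, prediction error variances and hat-diagonal
#' leverages come from the converged mixed-model equations.
#'
#' @param data data.frame holding the response, factor columns and an
#'   animal identifier column.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect factor columns (reference
#'   level dropped); an intercept is always included.
#' @param ped an [pedigree()] object; EBV are produced for every pedigree
#'   animal, with or without records.
#' @param animal name of the column linking records to pedigree labels.
#' @param permanent_env name of the grouping column for the
#'   permanent-environment term, or `NULL` to omit it.
#' @param resid_group optional column defining residual-variance groups
#'   (one variance estimated per group).
#' @param weights optional strictly positive per-record weights, interpreted
#'   as multipliers of the residual precision (variance of record i is
#'   `sigma2_e[g(i)] / weights[i]`).
#' @param start optional named list with elements `var_a`, `var_pe`, `var_e`
#'   (scalar or per-group vector) used as starting values, or as fixed
#'   values when `reml = FALSE`.
#' @param reml if `FALSE`, variance components are held at `start` and only
#'   BLUP/BLUE solutions are computed.
#' @param se if `TRUE`, asymptotic standard errors of the variance
#'   components are computed from the numerical REML information matrix.
#' @param maxit maximum number of L-BFGS-B iterations.
#' @param compute_pev,compute_leverage toggles for the (moderately costly)
#'   prediction-error-variance and leverage extraction.
#' @param on_nonconv "warn", "error" or "ignore" on REML non-convergence.
#' @return An object of class `lv_mm_fit`; a list with elements `vc`
#'   (variance components and their SEs), `beta`, `ebv` (named per pedigree
#'   animal), `pev`, `pe` (if fitted), `residuals`, `leverage`, `fitted`,
#'   `loglik`, `aliased` and `converged`.
#' @export
fit_animal_model <- function(data, response, fixed = NULL, ped,
                             animal = "animal", permanent_env = NULL,
                             resid_group = NULL, weights = NULL,
                             start = NULL, reml = TRUE, se = FALSE,
                             maxit = 200L, compute_pev = TRUE,
                             compute_leverage = TRUE, on_nonconv = "warn") {
  stopifnot(inherits(ped, "lv_pedigree"))
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  y <- data[[response]]
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("response must be numeric and finite", call. = FALSE)
  }
  n <- length(y)
  X <- mm_fixed_design(data, fixed, n)
  labels <- attr(ped, "labels")
  aidx <- match(as.character(data[[animal]]), labels)
  if (anyNA(aidx)) stop("animal id in data not present in pedigree", call. = FALSE)
  nA <- nrow(ped)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1, dims = c(n, nA))
  Ainv <- build_a_inverse(ped)
  terms <- list(mm_term("animal", Za, Kinv = Ainv, struct = "var1"))
  pe_levels <- NULL
  if (!is.null(permanent_env)) {
    fpe <- factor(as.character(data[[permanent_env]]))
    pe_levels <- levels(fpe)
    Zpe <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fpe), x = 1,
                                dims = c(n, nlevels(fpe)))
    terms <- c(terms, list(mm_term("pe", Zpe, struct = "var1")))
  }
  rg <- NULL
  ngroups <- 1L
  if (!is.null(resid_group)) {
    rg <- factor(data[[resid_group]])
    ngroups <- nlevels(rg)
  }
  vy <- stats::var(y)
  st <- list(var_a = 0.3 * vy, var_pe = 0.2 * vy, var_e = 0.5 * vy)
  if (!is.null(start)) st[names(start)] <- start
  term_vc <- list(st$var_a)
  if (!is.null(permanent_env)) term_vc <- c(term_vc, list(st$var_pe))
  resid_vc <- rep_len(st$var_e, ngroups)
  eng <- mm_engine(y, X, terms, rgroup = rg, rweights = weights,
                   start = list(term_vc = term_vc, resid_vc = resid_vc),
                   reml = reml, maxit = maxit, se = se,
                   compute_leverage = compute_leverage,
                   compute_pev = compute_pev, on_nonconv = on_nonconv)
  vc <- list(var_a = eng$vc$term_vc[[1]],
             var_pe = if (!is.null(permanent_env)) eng$vc$term_vc[[2]] else NULL,
             var_e = eng$vc$resid_vc)
  if (!is.null(rg)) names(vc$var_e) <- levels(rg)
  if (se && reml) {
    nt <- length(terms)
    vc$se <- list(
      var_a = mm_fun_se(eng, function(pp) exp(pp[1])),
      var_pe = if (nt > 1) mm_fun_se(eng, function(pp) exp(pp[2])) else NULL,
      var_e = vapply(seq_len(ngroups), function(g)
        mm_fun_se(eng, function(pp) exp(pp[nt + g])), numeric(1))
    )
  }
  ebv <- eng$u[["animal"]]
  names(ebv) <- labels
  pev <- if (!is.null(eng$pev)) eng$pev[["animal"]] else NULL
  if (!is.null(pev)) names(pev) <- labels
  pe_blup <- if (!is.null(permanent_env)) {
    stats::setNames(eng$u[["pe"]], pe_levels)
  } else NULL
  structure(list(
    vc = vc, beta = eng$beta, ebv = ebv, pev = pev, pe = pe_blup,
    fitted = eng$fitted, residuals = eng$residuals, leverage = eng$leverage,
    loglik = eng$loglik, aliased = eng$aliased, converged = eng$converged,
    engine = eng, animal_index = aidx, ped_labels = labels
  ), class = "lv_mm_fit")
}

# build the fixed-effect design matrix: intercept + treatment-coded factors
mm_fixed_design <- function(data, fixed, n) {
  if (is.null(fixed) || length(fixed) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  miss <- setdiff(fixed, names(data))
  if (length(miss)) stop("fixed-effect column(s) not found: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- data[fixed]
  df[] <- lapply(df, function(col) factor(as.character(col)))
  form <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
  stats::model.matrix(form, data = df)
}

#' @export
print.lv_mm_fit <- function(x, ...) {
  cat("Animal model fit:", length(x$ebv), "animals,",
      length(x$residuals), "records\n")
  cat("  var_a =", signif(x$vc$var_a, 4))
  if (!is.null(x$vc$var_pe)) cat(", var_pe =", signif(x$vc$var_pe, 4))
  cat(", var_e =", paste(signif(x$vc$var_e, 4), collapse = ", "), "\n")
  cat("  logLik =", signif(x$loglik, 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Heritability from variance components
#'
#' Ratio of additive genetic variance to total phenotypic variance of the
#' model terms. With grouped residual variances, the record-weighted mean
#' residual variance is used.
#'
#' @param var_a additive genetic variance.
#' @param var_e residual variance; scalar or per-group vector.
#' @param var_pe permanent-environment variance (0 if absent).
#' @param resid_weights optional record counts per residual group, used to
#'   weight `var_e` when it is a vector (defaults to equal weights).
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(var_a, var_e, var_pe = 0, resid_weights = NULL) {
  stopifnot(var_a >= 0, all(var_e >= 0), var_pe >= 0)
  if (length(var_e) > 1) {
    if (is.null(resid_weights)) resid_weights <- rep(1, length(var_e))
    var_e <- sum(var_e * resid_weights) / sum(resid_weights)
  }
  tot <- var_a + var_pe + var_e
  if (tot <= 0) stop("total variance must be positive", call. = FALSE)
  var_a / tot
}
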