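# Method-comparison machinery: theoretical accuracy of EBV, deregression of
# EBV for use as GWAS response variables, EBV correlation between methods,
# and three-fold paternal half-sib cross-validation.

#' Theoretical accuracy of an EBV
#'
#' `r = sqrt(1 - PEV / sigma2_add)`: 1 when the prediction error variance
#' is zero, 0 when it equals the additive variance. PEV marginally above
#' `sigma2_add` (numerical REML noise) is clipped to accuracy 0 with a
#' warning.
#'
#' @param pev prediction error variance(s).
#' @param sigma2_add additive genetic variance of the trait.
#' @return accuracy in `[0, 1]`, vectorised over `pev`.
#' @export
theoretical_accuracy <- function(pev, sigma2_add) {
  stopifnot(sigma2_add > 0, all(pev >= 0))
  ratio <- pev / sigma2_add
  if (any(ratio > 1)) {
    warning("PEV exceeds additive variance for ",
            sum(ratio > 1), " animal(s); accuracy clipped to 0",
            call. = FALSE)
    ratio <- pmin(ratio, 1)
  }
  sqrt(1 - ratio)
}

# scalar deregression system for one animal: given parent-average
# reliability r2_pa (on the individual scale, max 0.5) and individual
# reliability r2_i, split the information content between the parent
# average and the individual's own sources.
garrick_info_split <- function(r2_pa, r2_i, lambda) {
  r2_pa <- unname(r2_pa); r2_i <- unname(r2_i)
  alpha <- 1 / (0.5 - r2_pa)
  delta <- (0.5 - r2_pa) / (1 - r2_i)
  zz_pa <- lambda * (0.5 * alpha - 4) + 0.5 * lambda * sqrt(alpha^2 + 16 / delta)
  zz_i <- delta * (zz_pa + 4 * lambda) - 2 * lambda
  c(zz_pa = zz_pa, zz_i = zz_i)
}

#' Deregress EBV (Garrick-style information splitting)
#'
#' Removes the parent-average contribution from each animal's EBV so the
#' deregressed proofs can serve as independent GWAS response variables
#' without double-counting family information. For an animal with known
#' parents, the parent-average EBV and reliability are formed, the
#' two-equation information-splitting system is solved for the own-source
#' information content, and the deregressed EBV is the own-information
#' estimate. Animals with both parents unknown reduce to the classical
#' scalar deregression `dEBV = EBV / r2`. Weights
#' `w = (1 - h2) / ((c + (1 - r2_dEBV) / r2_dEBV) * h2)` are emitted for
#' optional weighted analyses.
#'
#' @param ebv named vector of EBV (names = pedigree labels).
#' @param pev named vector of prediction error variances (same animals).
#' @param ped the pedigree.
#' @param sigma2_add additive variance of the trait (reliability scale).
#' @param h2 heritability of the trait, in (0, 1).
#' @param c_frac fraction of genetic variance not accounted for by markers
#'   (enters the weights only).
#' @return data.frame `animal`, `debv`, `reliability` (of the dEBV),
#'   `weight`, `excluded` (TRUE when the animal carries no own information
#'   beyond its parent average).
#' @export
deregress_ebv <- function(ebv, pev, ped, sigma2_add, h2, c_frac = 0.5) {
  stopifnot(inherits(ped, "lv_pedigree"), h2 > 0, h2 < 1, sigma2_add > 0)
  labels <- attr(ped, "labels")
  idx <- match(names(ebv), labels)
  if (anyNA(idx)) stop("EBV names must match pedigree labels", call. = FALSE)
  r2 <- pmin(pmax(1 - pev / sigma2_add, 0), 1 - 1e-8)
  r2_all <- stats::setNames(rep(0, length(labels)), labels)
  ebv_all <- stats::setNames(rep(0, length(labels)), labels)
  r2_all[names(ebv)] <- r2
  ebv_all[names(ebv)] <- ebv
  lambda <- (1 - h2) / h2
  n <- length(ebv)
  debv <- rel <- wt <- rep(NA_real_, n)
  excl <- rep(FALSE, n)
  for (k in seq_len(n)) {
    i <- idx[k]
    s <- ped$sire[i]; d <- ped$dam[i]
    r2i <- r2[k]
    if (r2i <= 0) {
      excl[k] <- TRUE
      next
    }
    if (s == 0L && d == 0L) {
      debv[k] <- ebv[k] / r2i
      rel[k] <- r2i
    } else {
      r2s <- if (s > 0L) unname(r2_all[s]) else 0
      r2d <- if (d > 0L) unname(r2_all[d]) else 0
      g_pa <- 0.5 * unname((if (s > 0L) ebv_all[s] else 0) +
                           (if (d > 0L) ebv_all[d] else 0))
      r2_pa <- (r2s + r2d) / 4
      if (r2i <= r2_pa + 1e-9) {
        excl[k] <- TRUE
        next
      }
      zz <- garrick_info_split(r2_pa, r2i, lambda)
      if (zz[["zz_i"]] <= 0) {
        excl[k] <- TRUE
        next
      }
      # right-hand sides from the fitted values, then keep the own part
      y_i <- -2 * lambda * g_pa + (zz[["zz_i"]] + 2 * lambda) * unname(ebv[k])
      debv[k] <- y_i / zz[["zz_i"]]
      rel[k] <- 1 - lambda / (zz[["zz_i"]] + lambda)
    }
    wt[k] <- (1 - h2) / ((c_frac + (1 - rel[k]) / rel[k]) * h2)
  }
  data.frame(animal = names(ebv), debv = debv, reliability = rel,
             weight = wt, excluded = excl, stringsAsFactors = FALSE)
}

#' Correlate EBV from two methods
#'
#' Pearson correlation of the two EBV sets on their common animals, plus a
#' re-ranking summary (overlap of the top decile).
#'
#' @param ebv_a,ebv_b named EBV vectors.
#' @return list `correlation`, `n`, `top_decile_overlap`.
#' @export
compare_methods <- function(ebv_a, ebv_b) {
  common <- intersect(names(ebv_a), names(ebv_b))
  if (length(common) < 3) stop("fewer than 3 common animals", call. = FALSE)
  a <- ebv_a[common]; b <- ebv_b[common]
  k <- max(1L, floor(length(common) / 10))
  top_a <- names(sort(a, decreasing = TRUE))[seq_len(k)]
  top_b <- names(sort(b, decreasing = TRUE))[seq_len(k)]
  list(correlation = stats::cor(a, b), n = length(common),
       top_decile_overlap = length(intersect(top_a, top_b)) / k)
}

#' Three-fold paternal half-sib cross-validation
#'
#' Selects paternal families with at least `k` half-sisters with litter
#' records; in each of `k` folds one (disjointly chosen) half-sister per
#' family has all her records masked. Both variability pipelines (LnVar and
#' DHGLM) are re-fitted on the training records, and each masked sow's
#' predicted variability EBV is correlated with her realized
#' log-transformed variance of litter size computed from the masked
#' records. A paired one-sided t-test across folds compares the methods.
#'
#' @param records edited record table.
#' @param ped pedigree with records' sows.
#' @param k number of folds (and minimum half-sisters per family).
#' @param seed fold-assignment seed.
#' @param methods subset of `c("lnvar", "dhglm")`.
#' @param dhglm_args,lnvar_args lists of extra arguments passed to
#'   [run_dhglm()] / [lnvar_track()] (e.g. iteration caps).
#' @param min_masked warn when a fold masks fewer sows than this.
#' @return `lv_crossval` list: `folds` (per-fold masked sows and
#'   correlations), `summary` (per-method mean correlation), `t_test`
#'   (paired, one-sided, DHGLM more precise), `n_families`.
#' @export
run_cross_validation <- function(records, ped, k = 3L, seed = 1L,
                                 methods = c("lnvar", "dhglm"),
                                 dhglm_args = list(), lnvar_args = list(),
                                 min_masked = 30L) {
  methods <- match.arg(methods, several.ok = TRUE)
  labels <- attr(ped, "labels")
  sows <- unique(records$sow)
  sidx <- match(sows, labels)
  sire_of <- ped$sire[sidx]
  fam <- split(sows, sire_of)
  fam <- fam[names(fam) != "0"]
  fam <- fam[vapply(fam, length, 0L) >= k]
  if (length(fam) == 0) stop("no qualifying paternal families", call. = FALSE)
  set.seed(seed)
  masked <- lapply(fam, function(ss) sample(ss, k))
  fold_sows <- lapply(seq_len(k), function(j) vapply(masked, `[`, "", j))
  folds <- vector("list", k)
  for (j in seq_len(k)) {
    ms <- fold_sows[[j]]
    if (length(ms) < min_masked) {
      warning("fold ", j, " masks only ", length(ms), " sows", call. = FALSE)
    }
    train <- records[!records$sow %in% ms, , drop = FALSE]
    test <- records[records$sow %in% ms, , drop = FALSE]
    realized <- tapply(test$tnb, test$sow, function(x) log(stats::var(x)))
    realized <- realized[is.finite(realized)]
    cors <- list()
    if ("lnvar" %in% methods) {
      lt <- do.call(lnvar_track, c(list(records = train, ped = ped), lnvar_args))
      pred <- lt$var_fit$ebv[names(realized)]
      cors$lnvar <- stats::cor(pred, realized)
    }
    if ("dhglm" %in% methods) {
      dh <- do.call(run_dhglm, c(list(records = train, ped = ped), dhglm_args))
      pred <- stats::setNames(dh$ebv$ebv_var, dh$ebv$animal)[names(realized)]
      cors$dhglm <- stats::cor(pred, realized)
    }
    folds[[j]] <- list(masked = ms, n_masked = length(ms),
                       correlations = cors)
  }
  summ <- sapply(methods, function(m)
    mean(vapply(folds, function(f) f$correlations[[m]], numeric(1))))
  tt <- NULL
  if (all(c("lnvar", "dhglm") %in% methods)) {
    cl <- vapply(folds, function(f) f$correlations$lnvar, numeric(1))
    cd <- vapply(folds, function(f) f$correlations$dhglm, numeric(1))
    tt <- stats::t.test(cd, cl, paired = TRUE, alternative = "greater")
  }
  structure(list(folds = folds, summary = summ, t_test = tt,
                 n_families = length(fam)),
            class = "lv_crossval")
}

#' @export
print.lv_crossval <- function(x, ...) {
  cat("Cross-validation over", length(x$folds), "folds,",
      x$n_families, "paternal families\n")
  for (m in names(x$summary)) {
    cat(sprintf("  mean correlation (%s): %.3f\n", m, x$summary[[m]]))
  }
  if (!is.null(x$t_test)) {
    cat(sprintf("  paired t-test (DHGLM > LnVar): p = %.3f\n",
                x$t_test$p.value))
  }
  invisible(x)
}
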