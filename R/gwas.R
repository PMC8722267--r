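# Genotype QC, genomic relationship matrix, mixed-linear-model single-SNP
# association on deregressed EBV, SNP variance explained, LD, variance-QTL
# region calling, and the genomic inflation factor.

#' Construct a genotype object
#'
#' @param geno animals x SNPs matrix of dosages (0/1/2, NA = missing) with
#'   animal row names.
#' @param map data.frame with `snp`, `chrom`, `pos_bp` (one row per column
#'   of `geno`); `chrom` may contain "X"/"Y"/0/NA for non-autosomal or
#'   unmapped SNPs.
#' @return `lv_genotypes` object.
#' @export
genotypes <- function(geno, map) {
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno),
            all(c("snp", "chrom", "pos_bp") %in% names(map)))
  colnames(geno) <- map$snp
  structure(list(geno = geno, map = map), class = "lv_genotypes")
}

#' Hardy-Weinberg chi-square (1 df)
#'
#' Pearson goodness-of-fit statistic of the observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency.
#' Monomorphic SNPs return 0 by convention.
#'
#' @param n0,n1,n2 counts of the 0/1/2 dosage classes (vectorised).
#' @return chi-square statistic(s).
#' @export
hwe_chi2 <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  stopifnot(all(n > 0))
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- q^2 * n; e1 <- 2 * p * q * n; e2 <- p^2 * n
  chi <- ifelse(p <= 0 | p >= 1, 0,
                (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  as.numeric(chi)
}

#' Genotype quality control
#'
#' Drops SNPs with call rate below `call_rate`, minor allele frequency
#' below `maf`, Hardy-Weinberg chi-square above `hwe_chi2_max`, and SNPs
#' that are non-autosomal or unmapped; then drops animals with a
#' missing-genotype frequency above `animal_miss` (computed on the
#' retained panel).
#'
#' @param g an `lv_genotypes`.
#' @param call_rate,maf,hwe_chi2_max,animal_miss thresholds.
#' @param autosomes chromosome codes treated as autosomal; anything else
#'   (including NA) is dropped.
#' @return `lv_genotypes` with a `qc_report` attribute (counts per rule).
#' @export
qc_genotypes <- function(g, call_rate = 0.95, maf = 0.01,
                         hwe_chi2_max = 600, animal_miss = 0.05,
                         autosomes = NULL) {
  stopifnot(inherits(g, "lv_genotypes"))
  geno <- g$geno; map <- g$map
  n <- nrow(geno)
  chrom <- suppressWarnings(as.integer(as.character(map$chrom)))
  if (is.null(autosomes)) {
    mapped <- !is.na(chrom) & chrom >= 1
  } else {
    mapped <- as.character(map$chrom) %in% as.character(autosomes)
  }
  mapped <- mapped & !is.na(map$pos_bp)
  cr <- colMeans(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf_obs <- pmin(p, 1 - p)
  n0 <- colSums(geno == 0, na.rm = TRUE)
  n1 <- colSums(geno == 1, na.rm = TRUE)
  n2 <- colSums(geno == 2, na.rm = TRUE)
  hwe <- hwe_chi2(n0, n1, n2)
  keep <- mapped & cr >= call_rate & maf_obs >= maf & hwe <= hwe_chi2_max
  report <- list(
    n_snps_input = ncol(geno),
    dropped_unmapped = sum(!mapped),
    dropped_call_rate = sum(mapped & cr < call_rate),
    dropped_maf = sum(mapped & cr >= call_rate & maf_obs < maf),
    dropped_hwe = sum(mapped & cr >= call_rate & maf_obs >= maf &
                        hwe > hwe_chi2_max),
    n_snps_kept = sum(keep)
  )
  if (!any(keep)) stop("no SNPs survive quality control", call. = FALSE)
  geno <- geno[, keep, drop = FALSE]
  amiss <- rowMeans(is.na(geno))
  akeep <- amiss <= animal_miss
  report$dropped_animals <- sum(!akeep)
  report$n_animals_kept <- sum(akeep)
  out <- structure(list(geno = geno[akeep, , drop = FALSE],
                        map = map[keep, , drop = FALSE]),
                   class = "lv_genotypes")
  attr(out, "qc_report") <- report
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / (2 * sum p (1 - p))` with `M` the dosage matrix centred by
#' twice the observed allele frequency. Missing genotypes are mean-imputed
#' per SNP; monomorphic SNPs are excluded with a warning.
#'
#' @param g an `lv_genotypes` (ideally after [qc_genotypes()]).
#' @param standardize if `TRUE`, each SNP is additionally scaled by its own
#'   `sqrt(2 p (1 - p))` (VanRaden method 2 style) instead of the pooled
#'   denominator.
#' @return `lv_grm`: list `G` (dense symmetric matrix), `n_snps`.
#' @export
compute_grm <- function(g, standardize = FALSE) {
  stopifnot(inherits(g, "lv_genotypes"))
  geno <- g$geno
  p <- colMeans(geno, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from the GRM",
            call. = FALSE)
  }
  geno <- geno[, poly, drop = FALSE]
  p <- p[poly]
  M <- sweep(geno, 2, 2 * p)
  if (anyNA(M)) M[is.na(M)] <- 0  # mean imputation after centring
  if (standardize) {
    M <- sweep(M, 2, sqrt(2 * p * (1 - p)), "/")
    G <- tcrossprod(M) / ncol(M)
  } else {
    G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  }
  structure(list(G = G, n_snps = ncol(M)), class = "lv_grm")
}

# 1-D REML for the null model y = mu + u + e, u ~ N(0, G s2a), via the
# eigendecomposition of G; returns the variance components and the rotation
gwas_null_reml <- function(y, G, eig = NULL) {
  eg <- if (is.null(eig)) eigen(G, symmetric = TRUE) else eig
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  yt <- crossprod(U, y)
  ones <- crossprod(U, rep(1, length(y)))
  n <- length(y)
  m2ll <- function(log_ratio) {
    # ratio = s2a / s2e; profile out s2e and mu
    r <- exp(log_ratio)
    d <- r * lam + 1
    xtx <- sum(ones^2 / d)
    beta <- sum(ones * yt / d) / xtx
    rss <- sum((yt - ones * beta)^2 / d)
    s2e <- rss / (n - 1)
    (n - 1) * log(s2e) + sum(log(d)) + log(xtx) + rss / s2e
  }
  opt <- stats::optimize(m2ll, c(-12, 12))
  r <- exp(opt$minimum)
  d <- r * lam + 1
  xtx <- sum(ones^2 / d)
  beta <- sum(ones * yt / d) / xtx
  rss <- sum((yt - ones * beta)^2 / d)
  s2e <- rss / (n - 1)
  list(s2a = r * s2e, s2e = s2e, ratio = r, U = U, lambda = lam,
       yt = as.numeric(yt), ones = as.numeric(ones), mu = beta)
}

#' Mixed-linear-model single-SNP association scan
#'
#' Fits the null animal model `y* = mu + u* + e*` with `u* ~ N(0, G s2a)`
#' once by REML (eigendecomposition of the GRM), then tests each SNP by
#' generalized least squares with the null variance ratio held fixed
#' (EMMAX-style). Significance classes follow `p < 1e-6` (significant) and
#' `p < 1e-4` (suggestive).
#'
#' @param y_star response: a [deregress_ebv()] table or a named numeric
#'   vector of deregressed EBV.
#' @param g an `lv_genotypes` (QC'd); missing dosages are mean-imputed.
#' @param grm an `lv_grm` over (at least) the animals of `y_star`, or
#'   `NULL` to compute it from `g`.
#' @param p_significant,p_suggestive classification thresholds.
#' @param eig optional precomputed `eigen()` of the GRM over exactly the
#'   animals of `y_star` (in their order), reused across repeated scans of
#'   the same panel.
#' @return `lv_gwas` data.frame: per SNP `snp`, `chrom`, `pos_bp`, `freq`,
#'   `beta`, `se`, `p`, `sigma2_snp`, `share_genetic`, `share_phenotypic`,
#'   `class`; attributes `null_vc` (s2a, s2e) and `lambda_gc`.
#' @export
run_gwas <- function(y_star, g, grm = NULL,
                     p_significant = 1e-6, p_suggestive = 1e-4,
                     eig = NULL) {
  stopifnot(inherits(g, "lv_genotypes"))
  if (is.data.frame(y_star)) {
    keep <- !y_star$excluded & is.finite(y_star$debv)
    y <- stats::setNames(y_star$debv[keep], y_star$animal[keep])
  } else {
    y <- y_star[is.finite(y_star)]
  }
  common <- intersect(names(y), rownames(g$geno))
  if (length(common) < 10) stop("fewer than 10 animals with both response and genotypes",
                                call. = FALSE)
  y <- y[common]
  geno <- g$geno[common, , drop = FALSE]
  if (is.null(grm)) grm <- compute_grm(structure(list(geno = geno, map = g$map),
                                                 class = "lv_genotypes"))
  G <- grm$G
  if (!is.null(rownames(G))) G <- G[common, common]
  null <- gwas_null_reml(y, G, eig = eig)
  d <- null$ratio * null$lambda + 1
  w <- 1 / d
  Ut <- t(null$U)
  p_freq <- colMeans(geno, na.rm = TRUE) / 2
  m <- ncol(geno)
  beta <- se <- pval <- rep(NA_real_, m)
  poly <- p_freq > 0 & p_freq < 1
  cm <- colMeans(geno, na.rm = TRUE)
  genoi <- geno
  if (anyNA(genoi)) {
    nas <- which(is.na(genoi), arr.ind = TRUE)
    genoi[nas] <- cm[nas[, 2]]
  }
  Xt_all <- Ut %*% genoi          # rotated dosages
  ones <- null$ones
  yt <- null$yt
  sw_oo <- sum(w * ones * ones)
  sw_oy <- sum(w * ones * yt)
  for (j in which(poly)) {
    xt <- Xt_all[, j]
    sw_xx <- sum(w * xt * xt)
    sw_xo <- sum(w * xt * ones)
    sw_xy <- sum(w * xt * yt)
    # GLS with intercept: solve 2x2 normal equations
    det2 <- sw_oo * sw_xx - sw_xo^2
    if (det2 <= 0) next
    b <- (sw_oo * sw_xy - sw_xo * sw_oy) / det2
    mu <- (sw_xx * sw_oy - sw_xo * sw_xy) / det2
    rss <- sum(w * (yt - mu * ones - b * xt)^2)
    s2 <- rss / (length(y) - 2)
    vb <- s2 * sw_oo / det2
    beta[j] <- b
    se[j] <- sqrt(vb)
    pval[j] <- 2 * stats::pnorm(-abs(b / se[j]))
  }
  s2a <- null$s2a; s2P <- null$s2a + null$s2e
  sv <- snp_variance_explained(p_freq, beta, s2a, s2P)
  cls <- rep("null", m)
  cls[!is.na(pval) & pval < p_suggestive] <- "suggestive"
  cls[!is.na(pval) & pval < p_significant] <- "significant"
  out <- data.frame(
    snp = g$map$snp, chrom = g$map$chrom, pos_bp = g$map$pos_bp,
    freq = p_freq, beta = beta, se = se, p = pval,
    sigma2_snp = sv$sigma2_snp, share_genetic = sv$share_genetic,
    share_phenotypic = sv$share_phenotypic, class = cls,
    stringsAsFactors = FALSE
  )
  attr(out, "null_vc") <- c(s2a = s2a, s2e = null$s2e)
  attr(out, "lambda_gc") <- suppressWarnings(inflation_factor(pval[!is.na(pval)]))
  class(out) <- c("lv_gwas", "data.frame")
  out
}

#' Genetic and phenotypic variance explained by a SNP
#'
#' `sigma2_snp = 2 p q beta^2`; shares are the ratios to the additive and
#' the phenotypic variance.
#'
#' @param p allele frequency (of the counted allele).
#' @param beta allele substitution effect.
#' @param sigma2_a additive genetic variance of the response.
#' @param sigma2_P phenotypic variance of the response.
#' @return list `sigma2_snp`, `share_genetic`, `share_phenotypic`
#'   (vectorised).
#' @export
snp_variance_explained <- function(p, beta, sigma2_a, sigma2_P) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), sigma2_a > 0, sigma2_P > 0)
  s2 <- 2 * p * (1 - p) * beta^2
  list(sigma2_snp = s2,
       share_genetic = s2 / sigma2_a,
       share_phenotypic = s2 / sigma2_P)
}

#' Linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of genotype dosages (composite LD, suitable
#' for unphased data). `NA` if either SNP is monomorphic.
#'
#' @param g_i,g_j dosage vectors over the same animals.
#' @return r-squared in `[0, 1]` or `NA`.
#' @export
ld_r2 <- function(g_i, g_j) {
  ok <- is.finite(g_i) & is.finite(g_j)
  if (stats::sd(g_i[ok]) == 0 || stats::sd(g_j[ok]) == 0) return(NA_real_)
  stats::cor(g_i[ok], g_j[ok])^2
}

#' Call variance-QTL regions
#'
#' Every significant SNP seeds a region; suggestive SNPs on the same
#' chromosome join a region when their LD r-squared with the seed reaches
#' `r2_min`. Overlapping regions on the same chromosome are merged; the
#' index SNP is the member with the smallest p-value.
#'
#' @param results an `lv_gwas` table.
#' @param g the genotypes used for the scan (for LD).
#' @param r2_min minimum LD with the seed for a suggestive SNP to join.
#' @return data.frame of regions: `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `index_snp`, `index_p`, `snps` (comma-separated member ids).
#' @export
define_vqtl_regions <- function(results, g, r2_min = 0.2) {
  sig <- which(results$class == "significant")
  if (length(sig) == 0) {
    return(data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      index_snp = character(0), index_p = numeric(0),
                      snps = character(0)))
  }
  sug <- which(results$class == "suggestive")
  geno <- g$geno[, results$snp, drop = FALSE]
  members <- lapply(sig, function(s) {
    cand <- sug[results$chrom[sug] == results$chrom[s]]
    if (length(cand)) {
      r2 <- vapply(cand, function(j) ld_r2(geno[, s], geno[, j]), numeric(1))
      cand <- cand[!is.na(r2) & r2 >= r2_min]
    }
    sort(unique(c(s, cand)))
  })
  # merge regions sharing any member or overlapping in span
  merged <- list()
  for (mset in members) {
    hit <- which(vapply(merged, function(x) length(intersect(x, mset)) > 0, TRUE))
    if (length(hit)) {
      mset <- sort(unique(c(mset, unlist(merged[hit]))))
      merged[hit] <- NULL
    }
    merged <- c(merged, list(mset))
  }
  do.call(rbind, lapply(merged, function(idx) {
    ip <- idx[which.min(results$p[idx])]
    data.frame(chrom = results$chrom[ip],
               start_bp = min(results$pos_bp[idx]),
               end_bp = max(results$pos_bp[idx]),
               n_snps = length(idx),
               index_snp = results$snp[ip],
               index_p = results$p[ip],
               snps = paste(results$snp[idx], collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; about 1 for a
#' well-calibrated scan.
#'
#' @param pvalues vector of p-values in (0, 1]; at least 100 required.
#' @return the inflation factor lambda.
#' @export
inflation_factor <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 100) {
    warning("fewer than 100 p-values; lambda is unstable", call. = FALSE)
  }
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
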