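test_that("Hardy-Weinberg chi-square matches hand calculations", {
  expect_equal(hwe_chi2(25, 50, 25), 0)
  expect_equal(hwe_chi2(30, 40, 30), 4)
  expect_equal(hwe_chi2(50, 0, 50), 100)
  expect_equal(hwe_chi2(300, 0, 300), 600)
  expect_equal(hwe_chi2(10, 0, 0), 0)   # monomorphic convention
})

test_that("QC drops SNPs by MAF, HWE, call rate and mapping", {
  set.seed(3)
  n <- 700    # a het-free SNP has HWE chi-square ~n, over the 600 cutoff
  ok <- rbinom(n, 2, 0.4)
  low_maf <- rbinom(n, 2, 0.005)
  hwe_bad <- rep(c(0L, 2L), each = n / 2)       # no heterozygotes
  low_cr <- ok; low_cr[seq_len(0.1 * n)] <- NA
  geno <- cbind(ok = ok, low_maf = low_maf, hwe_bad = hwe_bad,
                low_cr = low_cr, sexchr = ok)
  rownames(geno) <- sprintf("an%03d", seq_len(n))
  map <- data.frame(snp = colnames(geno),
                    chrom = c(1, 1, 2, 2, "X"),
                    pos_bp = c(100, 200, 300, 400, 500))
  g <- genotypes(geno, map)
  qc <- qc_genotypes(g)
  expect_equal(colnames(qc$geno), "ok")
  rep <- attr(qc, "qc_report")
  expect_equal(rep$dropped_unmapped, 1)
  expect_equal(rep$dropped_call_rate, 1)
  expect_equal(rep$dropped_maf, 1)
  expect_equal(rep$dropped_hwe, 1)
  expect_equal(rep$n_snps_kept, 1)
})

test_that("GRM matches the dense VanRaden formula on a toy panel", {
  set.seed(8)
  geno <- matrix(rbinom(50, 2, 0.4), 5, 10)
  rownames(geno) <- paste0("a", 1:5)
  g <- genotypes(geno, data.frame(snp = paste0("s", 1:10), chrom = 1,
                                  pos_bp = 1:10))
  G <- compute_grm(g)$G
  p <- colMeans(geno) / 2
  M <- sweep(geno, 2, 2 * p)
  G0 <- M %*% t(M) / (2 * sum(p * (1 - p)))
  expect_equal(G, G0, ignore_attr = TRUE, tolerance = 1e-12)
  # identical animals have G_ij = G_ii
  geno2 <- rbind(geno, geno[1, ])
  rownames(geno2) <- paste0("a", 1:6)
  g2 <- genotypes(geno2, g$map)
  G2 <- compute_grm(g2)$G
  expect_equal(G2[1, 6], G2[1, 1])
})

test_that("GRM diagonal is ~1 for an unstructured HWE founder sample", {
  cfg <- sim_config(n_sires = 100, n_dams_per_sire = 4, n_generations = 1,
                    n_snps = 5000, maf_range = c(0.1, 0.5), seed = 7)
  ped <- simulate_pedigree(cfg)
  cfg$founder_ld_rho <- 0   # independent SNPs
  gt <- simulate_genotypes(ped, cfg)
  G <- compute_grm(gt)$G
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("LD r2 is the squared dosage correlation, allele-flip invariant", {
  g1 <- c(0, 0, 1, 1, 2, 2)
  g2 <- c(0, 1, 0, 1, 2, 2)
  expect_equal(ld_r2(g1, g2), 0.5625)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  expect_true(is.na(ld_r2(g1, rep(1, 6))))
})

test_that("adjacent SNPs show more LD than distant ones in simulated data", {
  cfg <- sim_config(n_sires = 50, n_dams_per_sire = 4, n_generations = 2,
                    n_snps = 300, n_chromosomes = 1, seed = 13)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  geno <- gt$geno
  set.seed(1)
  adj <- mean(sapply(seq_len(150), function(k) {
    j <- sample(ncol(geno) - 1, 1)
    ld_r2(geno[, j], geno[, j + 1])
  }), na.rm = TRUE)
  dist <- mean(sapply(seq_len(150), function(k) {
    j <- sample(ncol(geno), 2)
    if (abs(diff(j)) < 50) return(NA)
    ld_r2(geno[, j[1]], geno[, j[2]])
  }), na.rm = TRUE)
  expect_gt(adj, dist)
})

test_that("founder allele frequencies match the configured MAF", {
  cfg <- sim_config(n_sires = 125, n_dams_per_sire = 3, n_generations = 1,
                    n_snps = 200, maf_range = c(0.3, 0.3), seed = 21)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  n <- nrow(gt$geno)
  se3 <- 3 * sqrt(0.3 * 0.7 / (2 * n))
  freq <- colMeans(gt$geno) / 2
  # per-SNP frequency within 3 binomial SE of the target for ~99.7% of SNPs
  expect_gt(mean(abs(freq - 0.3) <= se3), 0.95)
  # offspring of two 0/0 parents are 0 (Mendelian forcing checked in bulk)
  expect_true(all(gt$geno %in% 0:2))
})

test_that("SNP variance explained reproduces the closed form", {
  sv <- snp_variance_explained(0.49, 0.019, sigma2_a = 0.012, sigma2_P = 0.06)
  expect_equal(round(sv$share_genetic, 3), 0.015)
  sv2 <- snp_variance_explained(0.48, 0.020, sigma2_a = 0.014, sigma2_P = 0.06)
  expect_equal(round(sv2$share_genetic, 3), 0.014)
  expect_equal(snp_variance_explained(0, 0.5, 1, 1)$sigma2_snp, 0)
  # maximal at p = 0.5 for fixed beta, zero at the boundaries
  p <- seq(0, 1, 0.05)
  s <- snp_variance_explained(p, 0.1, 1, 1)$sigma2_snp
  expect_equal(p[which.max(s)], 0.5)
  expect_equal(s[c(1, length(s))], c(0, 0))
})

test_that("inflation factor is calibrated", {
  expect_equal(inflation_factor(rep(0.5, 200)), 1)
  set.seed(4)
  p_unif <- runif(10000)
  lam <- inflation_factor(p_unif)
  expect_gt(lam, 0.95); expect_lt(lam, 1.05)
  # doubling every chi-square doubles lambda
  chi <- qchisq(p_unif, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(inflation_factor(p2) / lam, 2, tolerance = 0.05)
  expect_error(inflation_factor(c(rep(0.5, 200), 0)), "0, 1")
})

test_that("GWAS with identity GRM equals single-SNP OLS", {
  set.seed(15)
  n <- 150
  geno <- matrix(rbinom(n * 20, 2, 0.35), n, 20)
  rownames(geno) <- sprintf("id%03d", seq_len(n))
  g <- genotypes(geno, data.frame(snp = paste0("s", 1:20), chrom = 1,
                                  pos_bp = seq_len(20) * 1000))
  y <- setNames(0.12 * geno[, 7] + rnorm(n, 0, 0.3), rownames(geno))
  grm <- structure(list(G = diag(n), n_snps = 0), class = "lv_grm")
  rownames(grm$G) <- colnames(grm$G) <- rownames(geno)
  res <- run_gwas(y, g, grm)
  ols <- sapply(seq_len(20), function(j) coef(lm(y ~ geno[, j]))[2])
  expect_equal(res$beta, unname(ols), tolerance = 1e-6)
})

test_that("vQTL regions follow the significant + linked-suggestive rule", {
  # 1 significant SNP, 2 linked suggestive, 1 unlinked suggestive, 1 other chr
  set.seed(6)
  n <- 400
  base <- rbinom(n, 2, 0.5)
  flip <- function(g, k) { i <- sample(n, k); g[i] <- 2 - g[i]; g }
  geno <- cbind(sig = base, link1 = flip(base, 20), link2 = flip(base, 30),
                unlinked = rbinom(n, 2, 0.5), other = rbinom(n, 2, 0.5))
  rownames(geno) <- sprintf("a%03d", seq_len(n))
  map <- data.frame(snp = colnames(geno), chrom = c(1, 1, 1, 1, 2),
                    pos_bp = c(100, 200, 300, 4000, 100))
  res <- data.frame(snp = map$snp, chrom = map$chrom, pos_bp = map$pos_bp,
                    p = c(1e-8, 1e-5, 2e-5, 1e-5, 1e-5),
                    class = c("significant", rep("suggestive", 4)))
  g <- genotypes(geno, map)
  regions <- define_vqtl_regions(res, g, r2_min = 0.2)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$n_snps, 3)
  expect_equal(regions$index_snp, "sig")
  expect_equal(sort(strsplit(regions$snps, ",")[[1]]),
               c("link1", "link2", "sig"))
  # no significant SNPs: no regions
  res0 <- res; res0$class[1] <- "suggestive"
  expect_equal(nrow(define_vqtl_regions(res0, g)), 0)
})
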