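# Simulation of pedigree, genotypes and repeated litter-size records under
# the exponential micro-environmental variance model
#   y = mu + fixed + u + pe + exp(0.5 * (eta + v + pe_v)) * eps,
# with bivariate additive effects (u, v) propagated through the pedigree and
# bivariate permanent-environment effects (pe, pe_v) per sow.

#' Simulation configuration
#'
#' Collects all parameters of the synthetic litter-size study. Defaults
#' reproduce the statistical structure of a commercial Large White
#' population: mean litter size 13.76 piglets, additive variance 1.33 and
#' permanent-environment variance 0.86 for the mean part, residual variance
#' 7.67 (so `eta = log(7.67)`), variance-part additive variance 0.037 and
#' permanent-environment variance 0.15, genetic correlation 0.43 and
#' permanent-environment correlation -0.87 between mean and variance parts.
#'
#' @param n_sires sires per generation.
#' @param n_dams_per_sire dams mated to each sire per generation.
#' @param n_generations total number of generations (1 = founders only).
#' @param litters_per_sow_range integer `c(min, max)` litters per sow;
#'   minimum must be at least 2 so within-sow variances exist.
#' @param mu population mean of TNB (piglets).
#' @param eta log mean environmental variance.
#' @param var_a,var_av additive variances of the mean (`u`) and variance
#'   (`v`) parts.
#' @param r_a_av genetic correlation between `u` and `v`.
#' @param var_pe,var_pev,r_pe_pev permanent-environment analogues.
#' @param parity_effects numeric vector of fixed parity effects (recycled /
#'   truncated to 10 parities); the default is a concave parity curve.
#' @param n_hys number of herd-year-season levels.
#' @param hys_sd standard deviation of the herd-year-season effects.
#' @param n_snps,n_chromosomes SNP panel size and chromosome count.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param recomb_rate per-adjacent-SNP recombination probability.
#' @param founder_ld_rho AR(1) parameter of the latent Gaussian field that
#'   induces linkage disequilibrium among founder haplotypes.
#' @param causal_snp `NULL`, or `list(index, beta_v, beta_u)` planting a
#'   QTL whose genotype dosage is added to `v` (and optionally `u`).
#' @param integer_phenotype if `TRUE`, records are rounded and clamped to
#'   the integer litter-size support `[0, 30]`; continuous by default.
#' @param seed integer seed; all randomness derives from it.
#' @return a validated list of class `lv_sim_config`.
#' @export
sim_config <- function(n_sires = 25L, n_dams_per_sire = 20L,
                       n_generations = 3L,
                       litters_per_sow_range = c(2L, 10L),
                       mu = 13.76, eta = log(7.67),
                       var_a = 1.33, var_av = 0.037, r_a_av = 0.43,
                       var_pe = 0.86, var_pev = 0.15, r_pe_pev = -0.87,
                       parity_effects = c(0, 0.9, 1.4, 1.6, 1.5,
                                          1.2, 0.8, 0.4, 0, -0.5),
                       n_hys = 20L, hys_sd = 0.5,
                       n_snps = 2000L, n_chromosomes = 5L,
                       maf_range = c(0.05, 0.5), recomb_rate = 0.01,
                       founder_ld_rho = 0.9,
                       causal_snp = NULL,
                       integer_phenotype = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  if (n_sires < 1 || n_dams_per_sire < 1 || n_generations < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (litters_per_sow_range[1] < 2) {
    stop("litters_per_sow_range minimum must be >= 2", call. = FALSE)
  }
  for (v in c("var_a", "var_av", "var_pe", "var_pev")) {
    if (cfg[[v]] < 0) stop(v, " must be >= 0", call. = FALSE)
  }
  for (r in c("r_a_av", "r_pe_pev")) {
    if (abs(cfg[[r]]) > 1) stop(r, " must be in [-1, 1]", call. = FALSE)
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (!is.null(causal_snp)) {
    stopifnot(is.list(causal_snp), !is.null(causal_snp$index))
    if (is.null(causal_snp$beta_u)) cfg$causal_snp$beta_u <- 0
    if (is.null(causal_snp$beta_v)) cfg$causal_snp$beta_v <- 0
  }
  class(cfg) <- "lv_sim_config"
  cfg
}

# lower Cholesky-like factor of a 2x2 covariance, tolerating zero variances
chol_psd2 <- function(v1, v2, r) {
  s1 <- sqrt(v1); s2 <- sqrt(v2)
  L <- matrix(0, 2, 2)
  L[1, 1] <- s1
  L[2, 1] <- r * s2
  L[2, 2] <- s2 * sqrt(max(0, 1 - r^2))
  L
}

#' Simulate a multi-generation half-sib pedigree
#'
#' Generation 1 consists of founder sires and dams (unknown parents); each
#' later generation is produced by mating every sire of the previous
#' generation to its assigned dams, yielding replacement sires and dams so
#' that every generation has `n_sires` males and
#' `n_sires * n_dams_per_sire` females.
#'
#' @param config an [sim_config()].
#' @return an [pedigree()] with `sex` and `generation` metadata columns.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "lv_sim_config"))
  set.seed(config$seed + 1L)
  S <- config$n_sires
  D <- S * config$n_dams_per_sire
  G <- config$n_generations
  id <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); gen <- integer(0)
  prev_m <- prev_f <- character(0)
  for (g in seq_len(G)) {
    males <- sprintf("G%d_M%03d", g, seq_len(S))
    females <- sprintf("G%d_F%04d", g, seq_len(D))
    kids <- c(males, females)
    if (g == 1L) {
      ks <- rep("0", length(kids)); kd <- rep("0", length(kids))
    } else {
      # each previous-generation sire gets n_dams_per_sire dams
      dam_of <- split(sample(prev_f), rep(seq_len(S), config$n_dams_per_sire))
      mating_sire <- sample(S, length(kids), replace = TRUE)
      ks <- prev_m[mating_sire]
      kd <- vapply(mating_sire, function(s) sample(dam_of[[s]], 1L), "")
    }
    id <- c(id, kids); sire <- c(sire, ks); dam <- c(dam, kd)
    sex <- c(sex, rep(c("M", "F"), c(S, D)))
    gen <- c(gen, rep(g, length(kids)))
    prev_m <- males; prev_f <- females
  }
  pedigree(id, sire, dam, sex = sex, generation = gen)
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn with allele frequencies sampled from
#' `maf_range` and with linkage disequilibrium induced by a latent AR(1)
#' Gaussian field along each chromosome. Descendant haplotypes are produced
#' by gene dropping: each gamete picks one parental haplotype per
#' chromosome and switches haplotype between adjacent SNPs with the
#' configured recombination probability (no interference).
#'
#' @param ped an [pedigree()].
#' @param config an [sim_config()].
#' @return object of class `lv_genotypes`: list with `geno` (animals x SNPs
#'   integer dosage matrix, 0/1/2 counted alleles), `map` (data.frame with
#'   `snp`, `chrom`, `pos_bp`) and `founder_freq`.
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "lv_pedigree"), inherits(config, "lv_sim_config"))
  set.seed(config$seed + 2L)
  m <- config$n_snps
  stopifnot(m >= 1)
  nc <- config$n_chromosomes
  chrom <- sort(rep(seq_len(nc), length.out = m))
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 50000L
  map <- data.frame(snp = sprintf("snp%05d", seq_len(m)),
                    chrom = chrom, pos_bp = pos)
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  n <- nrow(ped)
  labels <- attr(ped, "labels")
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  chrom_start <- !duplicated(chrom)
  thr <- stats::qnorm(p)
  rho <- config$founder_ld_rho
  founder_hap <- function() {
    z <- numeric(m)
    e <- stats::rnorm(m)
    for (j in seq_len(m)) {
      z[j] <- if (chrom_start[j]) e[j] else rho * z[j - 1L] + sqrt(1 - rho^2) * e[j]
    }
    as.integer(z < thr)
  }
  gamete <- function(h1, h2) {
    sw <- stats::runif(m) < config$recomb_rate
    sw[chrom_start] <- stats::runif(sum(chrom_start)) < 0.5
    use2 <- cumsum(sw) %% 2L
    # reset the parity at each chromosome start so chromosomes segregate
    # independently: cumsum over the whole vector already re-randomises at
    # each start via the Bernoulli(1/2) above
    ifelse(use2 == 1L, h2, h1)
  }
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    H1[i, ] <- if (s > 0L) gamete(H1[s, ], H2[s, ]) else founder_hap()
    H2[i, ] <- if (d > 0L) gamete(H1[d, ], H2[d, ]) else founder_hap()
  }
  geno <- H1 + H2
  dimnames(geno) <- list(labels, map$snp)
  structure(list(geno = geno, map = map, founder_freq = p,
                 counted_allele = rep("B", m)),
            class = "lv_genotypes")
}

#' Simulate repeated litter-size records
#'
#' Draws bivariate additive effects (u, v) through the pedigree (parent
#' average plus Mendelian sampling scaled by `0.5 * (1 - (F_s + F_d) / 2)`),
#' bivariate permanent-environment effects per sow, optional planted-QTL
#' contributions from a genotype, and generates per-parity records under
#' the exponential residual-variance model.
#'
#' @param ped an [pedigree()] with a `sex` column; all females become sows
#'   with records.
#' @param config an [sim_config()].
#' @param genotypes optional [simulate_genotypes()] result; required when
#'   `config$causal_snp` is set.
#' @return list with `records` (data.frame `sow`, `parity`, `hys`, `tnb`)
#'   and `truth` (list: `animals` data.frame of true effects, `record_sd`
#'   true per-record residual SDs, `causal`, `config`).
#' @export
simulate_phenotypes <- function(ped, config, genotypes = NULL) {
  stopifnot(inherits(ped, "lv_pedigree"), inherits(config, "lv_sim_config"))
  if (!is.null(config$causal_snp) && is.null(genotypes)) {
    stop("causal_snp configured but no genotypes supplied", call. = FALSE)
  }
  set.seed(config$seed + 3L)
  n <- nrow(ped)
  labels <- attr(ped, "labels")
  La <- chol_psd2(config$var_a, config$var_av, config$r_a_av)
  Lp <- chol_psd2(config$var_pe, config$var_pev, config$r_pe_pev)
  uv <- matrix(0, n, 2)
  f <- ped$f
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    z <- stats::rnorm(2)
    if (s > 0L && d > 0L) {
      pa <- 0.5 * (uv[s, ] + uv[d, ])
      msv <- 0.5 * (1 - (f[s] + f[d]) / 2)
    } else if (s > 0L || d > 0L) {
      k <- max(s, d)
      pa <- 0.5 * uv[k, ]
      msv <- 0.75 - 0.25 * f[k]
    } else {
      pa <- c(0, 0)
      msv <- 1
    }
    uv[i, ] <- pa + sqrt(msv) * as.numeric(La %*% z)
  }
  causal <- NULL
  if (!is.null(config$causal_snp)) {
    cs <- config$causal_snp
    g <- genotypes$geno[, cs$index]
    uv[, 1] <- uv[, 1] + cs$beta_u * g
    uv[, 2] <- uv[, 2] + cs$beta_v * g
    causal <- list(index = cs$index, snp = genotypes$map$snp[cs$index],
                   beta_u = cs$beta_u, beta_v = cs$beta_v)
  }
  is_sow <- if ("sex" %in% names(ped)) ped$sex == "F" else rep(TRUE, n)
  pe <- matrix(NA_real_, n, 2)
  sow_idx <- which(is_sow)
  pe[sow_idx, ] <- t(Lp %*% matrix(stats::rnorm(2 * length(sow_idx)),
                                   2, length(sow_idx)))
  litter_counts <- seq(config$litters_per_sow_range[1],
                       config$litters_per_sow_range[2])
  nlit <- litter_counts[sample.int(length(litter_counts), length(sow_idx),
                                   replace = TRUE)]
  hys_eff <- stats::rnorm(config$n_hys, 0, config$hys_sd)
  par_eff <- rep_len(config$parity_effects, 10L)
  rec_sow <- rep(sow_idx, nlit)
  parity <- unlist(lapply(nlit, seq_len), use.names = FALSE)
  hys <- sample.int(config$n_hys, length(rec_sow), replace = TRUE)
  sd_rec <- exp(0.5 * (config$eta + uv[rec_sow, 2] + pe[rec_sow, 2]))
  tnb <- config$mu + par_eff[pmin(parity, 10L)] + hys_eff[hys] +
    uv[rec_sow, 1] + pe[rec_sow, 1] + sd_rec * stats::rnorm(length(rec_sow))
  if (config$integer_phenotype) {
    tnb <- pmin(pmax(round(tnb), 0), 30)
  }
  records <- data.frame(
    sow = labels[rec_sow],
    parity = parity,
    hys = sprintf("hys%02d", hys),
    tnb = tnb,
    stringsAsFactors = FALSE
  )
  truth <- list(
    animals = data.frame(id = labels, u = uv[, 1], v = uv[, 2],
                         pe = pe[, 1], pe_v = pe[, 2],
                         stringsAsFactors = FALSE),
    record_sd = sd_rec,
    causal = causal,
    config = config
  )
  list(records = records, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()] (optional) and [simulate_phenotypes()] under one
#' configuration.
#'
#' @param config an [sim_config()].
#' @param genotypes logical; simulate the SNP panel too?
#' @return list with `ped`, `genotypes` (or `NULL`), `records`, `truth`.
#' @export
simulate_dataset <- function(config, genotypes = FALSE) {
  ped <- simulate_pedigree(config)
  gt <- if (genotypes || !is.null(config$causal_snp)) {
    simulate_genotypes(ped, config)
  } else NULL
  ph <- simulate_phenotypes(ped, config, gt)
  list(ped = ped, genotypes = gt, records = ph$records, truth = ph$truth)
}

#' Write a simulated dataset as tab-delimited text
#'
#' Emits `pedigree.tsv` (id, sire, dam; 0 = unknown), `phenotypes.tsv`
#' (sow, parity, hys, tnb), `truth_animals.tsv`, and, when genotypes are
#' present, `genotypes.tsv` (animals x SNPs dosage matrix) plus `map.tsv`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- attr(sim$ped, "labels")
  pd <- data.frame(id = labels,
                   sire = ifelse(sim$ped$sire > 0, labels[pmax(sim$ped$sire, 1)], "0"),
                   dam = ifelse(sim$ped$dam > 0, labels[pmax(sim$ped$dam, 1)], "0"))
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(files, wr(pd, "pedigree.tsv"))
  files <- c(files, wr(sim$records, "phenotypes.tsv"))
  files <- c(files, wr(sim$truth$animals, "truth_animals.tsv"))
  if (!is.null(sim$genotypes)) {
    gd <- data.frame(id = rownames(sim$genotypes$geno),
                     sim$genotypes$geno, check.names = FALSE)
    files <- c(files, wr(gd, "genotypes.tsv"))
    files <- c(files, wr(sim$genotypes$map, "map.tsv"))
  }
  invisible(files)
}
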