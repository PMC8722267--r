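test_that("pedigree counts are forced by the configuration", {
  cfg <- sim_config(n_sires = 2, n_dams_per_sire = 2, n_generations = 2,
                    seed = 1)
  ped <- simulate_pedigree(cfg)
  # per generation: 2 sires + 4 dams; founders = generation 1
  expect_equal(nrow(ped), 12)
  expect_equal(sum(ped$sire == 0 & ped$dam == 0), 6)
  # topological order: parents precede offspring (construction validates,
  # re-check explicitly)
  expect_true(all(ped$sire < seq_len(nrow(ped))))
  expect_true(all(ped$dam < seq_len(nrow(ped))))
})

test_that("seeded simulation is exactly reproducible", {
  cfg <- sim_config(n_sires = 4, n_dams_per_sire = 4, n_generations = 2,
                    n_snps = 50, seed = 99)
  s1 <- simulate_dataset(cfg, genotypes = TRUE)
  s2 <- simulate_dataset(cfg, genotypes = TRUE)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$genotypes$geno, s2$genotypes$geno)
  expect_identical(s1$truth$animals, s2$truth$animals)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(litters_per_sow_range = c(1, 5)), ">= 2")
  expect_error(sim_config(var_a = -1), ">= 0")
  expect_error(sim_config(r_a_av = 1.2), "\\[-1, 1\\]")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_sires = 0), ">= 1")
})

test_that("null variance genetics collapses to a homoscedastic model", {
  cfg <- sim_config(n_sires = 20, n_dams_per_sire = 10, n_generations = 2,
                    var_av = 0, var_pev = 0, r_a_av = 0, r_pe_pev = 0,
                    litters_per_sow_range = c(6, 6), seed = 17)
  sim <- simulate_dataset(cfg)
  # all true record SDs identical
  expect_equal(stats::sd(sim$truth$record_sd), 0)
  expect_equal(unique(sim$truth$record_sd)^2, 7.67, tolerance = 1e-12)
  # Levene-type check: group records by sow record-count strata and test
  # equality of within-sow variances against heteroscedastic alternative
  rec <- sim$records
  fit <- suppressWarnings(
    fit_animal_model(rec, "tnb", fixed = c("hys", "parity"), ped = sim$ped,
                     animal = "sow", permanent_env = "sow",
                     compute_pev = FALSE, compute_leverage = FALSE))
  res <- split(fit$residuals, rec$sow)
  lv <- compute_lnvar_phenotype(res)
  grp <- cut(seq_len(nrow(lv)), 4)
  expect_gt(stats::kruskal.test(lv$lnvar, grp)$p.value, 0.01)
})

test_that("phenotypic variance matches the sum of simulated components", {
  cfg <- sim_config(n_sires = 25, n_dams_per_sire = 16, n_generations = 2,
                    litters_per_sow_range = c(5, 5), hys_sd = 0,
                    parity_effects = rep(0, 10), seed = 27)
  sim <- simulate_dataset(cfg)
  # var = var_a + var_pe + exp(eta + (var_av + var_pev)/2); founder-heavy
  # pedigree keeps the additive variance near its base value
  expected <- 1.33 + 0.86 + 7.67 * exp((0.037 + 0.15) / 2)
  expect_equal(stats::var(sim$records$tnb), expected, tolerance = 0.05)
  expect_equal(mean(sim$records$tnb), 13.76, tolerance = 0.01)
})

test_that("true breeding-value correlation matches the configured r_a_av", {
  cfg <- sim_config(n_sires = 60, n_dams_per_sire = 20, n_generations = 3,
                    seed = 33)
  ped <- simulate_pedigree(cfg)
  ph <- simulate_phenotypes(ped, cfg)
  tr <- ph$truth$animals
  expect_equal(cor(tr$u, tr$v), 0.43, tolerance = 0.03)
  # founder means of u and v are ~0
  founders <- ped$sire == 0 & ped$dam == 0
  expect_lt(abs(mean(tr$u[founders])), 3 * sqrt(1.33 / sum(founders)))
  expect_lt(abs(mean(tr$v[founders])), 3 * sqrt(0.037 / sum(founders)))
})

test_that("planted causal SNP shifts the variance part", {
  cfg <- sim_config(n_sires = 40, n_dams_per_sire = 10, n_generations = 2,
                    n_snps = 100, causal_snp = list(index = 50, beta_v = 0.3),
                    seed = 41)
  sim <- simulate_dataset(cfg)
  g <- sim$genotypes$geno[, 50]
  v <- sim$truth$animals$v
  expect_gt(coef(lm(v ~ g))[2], 0.2)
  expect_equal(sim$truth$causal$index, 50)
})

test_that("written dataset files round-trip", {
  sim <- simulate_dataset(sim_config(n_sires = 3, n_dams_per_sire = 3,
                                     n_generations = 2, n_snps = 20,
                                     seed = 51), genotypes = TRUE)
  dir <- file.path(tempdir(), "simdata_rt")
  write_sim_data(sim, dir)
  ped2 <- read_pedigree_tsv(file.path(dir, "pedigree.tsv"))
  expect_equal(attr(ped2, "labels"), attr(sim$ped, "labels"))
  expect_equal(ped2$sire, sim$ped$sire)
  rec2 <- read_records_tsv(file.path(dir, "phenotypes.tsv"))
  expect_equal(rec2$tnb, sim$records$tnb, tolerance = 1e-12)
  gt2 <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"),
                            file.path(dir, "map.tsv"))
  expect_equal(unname(gt2$geno), unname(sim$genotypes$geno))
})
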