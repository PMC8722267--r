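# littervar

Quantitative-genetic analysis of **litter-size variability** in pig
breeding populations. Litter size (total number born, TNB) is under
genetic control in its mean *and* in its variability around that mean;
sows differ heritably in how uniform their litters are, and loci
associated with that variability are called **variance QTL (vQTL)**.
`littervar` is aimed at animal-breeding researchers who want to estimate
micro-environmental sensitivity of litter size, compare the two standard
variability phenotypes, and scan for vQTL — on their own pedigree /
phenotype / genotype files or on the package's built-in simulator.

## What it implements

Two routes to a per-sow variability phenotype, built on one sparse
pedigree REML/BLUP engine (Henderson's mixed-model equations,
Meuwissen–Luo inbreeding, heterogeneous residual groups, per-record
weights):

* **LnVar** — fit the repeatability animal model
  `y = Xb + Za + U pe + e`, take each sow's residuals, and analyse
  `LnVarTNB = log(var(residuals))` with a second animal model whose
  residual variance is specific to nine record-count groups.
* **DHGLM** — a double hierarchical generalized linear model: the mean
  part and a variance part (log residual variance per record) are fitted
  jointly, coupled by the 2×2 additive covariance `[[σ²_a, σ_a,av],
  [σ_a,av, σ²_av]] ⊗ A` and its permanent-environment analogue, iterating
  the residual weights `W = diag(exp(ψ̂))⁻¹`, `W_v = diag((1−h)/2)` to
  convergence. The variance-part breeding values are the second
  variability phenotype (varTNB).

Downstream: theoretical accuracy `r = sqrt(1 − PEV/σ²_a)`, Garrick-style
deregression of EBV (information splitting; weights
`w = (1−h²)/((c + (1−r²)/r²) h²)`), three-fold paternal half-sib
cross-validation, genotype QC (call rate, MAF, Hardy–Weinberg χ²,
autosomes), VanRaden GRM, a mixed-linear-model single-SNP scan on
deregressed EBV with the null variance ratio held fixed, per-SNP variance
explained `σ²_snp = 2pq β̂²`, LD-based vQTL region calling and the genomic
inflation factor λ. A seeded simulator generates pedigrees, gene-dropped
genotypes with LD, and repeated litter records under the exponential
variance model `y = μ + u + exp(½(η + v)) ε`, with an optional planted
vQTL and a truth set for parameter-recovery studies.

## Worked example

```r
library(littervar)

cfg <- sim_config(n_sires = 15, n_dams_per_sire = 12, n_generations = 3,
                  seed = 5)                 # ~540 sows, ~3,250 records
sim <- simulate_dataset(cfg)
rec <- apply_edit_rules(sim$records)        # TNB <= 3 dropped, 25+ capped, ...

fit <- fit_animal_model(rec, "tnb", fixed = c("hys", "parity"),
                        ped = sim$ped, animal = "sow", permanent_env = "sow")
fit
#> Animal model fit: 585 animals, 3253 records
#>   var_a = 1.347, var_pe = 0.8292, var_e = 7.766
#>   logLik = -5230.07 (converged)

heritability(fit$vc$var_a, fit$vc$var_e, fit$vc$var_pe)
#> [1] 0.1355231

dh <- run_dhglm(rec, sim$ped)   # ~2 min at this herd size
dh
#> DHGLM fit (21 iterations, converged)
#>   additive:  var_a = 1.36  var_av = 0.01699  r = 0.623
#>   perm env:  var_pe = 0.8746  var_pev = 0.2845  r = -0.546
#>   scaling variances: 0.9997 0.7447

100 * gcv_sde(dh$Ga[2, 2])   # % change in residual SD per genetic SD
#> [1] 6.516955
```

The simulation was generated with additive variance 1.33, permanent
environment 0.86, residual variance 7.67 — the mean-model fit recovers
them (heritability 0.136). The DHGLM then estimates the variance-part
components: at ~540 sows the additive variance of the variance part
(`var_av`, simulated as 0.037) is the least-determined parameter and its
point estimate (here 0.017) scatters over a wide range seed to seed,
while the correlations (simulated 0.43 and −0.87) and the mean-part
components are recovered with usable precision; the mean-part scaling
variance sits at 1 as it should (the vignette explains why the
variance-part scaling sits below 1 at this leverage level). The full pipeline (both tracks,
deregression, GWAS on both deregressed EBV sets, region calling, report)
runs from one config:

```r
out <- run_pipeline(pipeline_config(outdir = "demo_run", seed = 1,
         simulate = sim_config(causal_snp = list(index = 1000, beta_v = 0.3),
                               seed = 1)))
readLines(file.path(out, "summary.txt"))
```

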