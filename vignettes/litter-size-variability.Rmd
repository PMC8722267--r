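---
title: "Modelling the genetic control of litter-size variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the genetic control of litter-size variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(littervar)
```

## The problem

Litter size in pigs (total number born, TNB) is under genetic control not
only in its mean but also in its variability: some sows produce litters of
consistent size, others fluctuate strongly between parities. If part of
that difference is heritable, breeding can select for uniformity, and loci
that control variability (variance QTL, vQTL) can be mapped. `littervar`
implements the two standard routes to a per-sow variability phenotype and
everything needed to compare them and run a vQTL scan on simulated or user
data.

## Models

### Mean model (repeatability animal model)

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Za} + \mathbf{U\,pe} + \mathbf{e},$$

with fixed herd-year-season and parity effects, additive genetic effects
$\mathbf{a} \sim N(\mathbf{0}, \mathbf{A}\sigma^2_a)$ (pedigree numerator
relationship matrix $\mathbf{A}$), permanent sow environment
$\mathbf{pe} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_{pe})$ for repeated
litters, and i.i.d. residuals.

### LnVar: log-transformed variance of residuals

The residuals of the mean model are grouped per sow; the variability
phenotype is the log of the within-sow sample variance (denominator
$n-1$; the underlying literature does not fix the denominator, and the
unbiased form is used here). That phenotype is analysed with a second
animal model whose fixed effect is the herd-year-season of the sow's first
farrowing and whose residual variance is heterogeneous over nine groups
defined by the number of records (2, 3, ..., 9, 10+): a sow with more
litters estimates her own variance more precisely. Sows with exactly zero
residual variance carry no information on the log scale and are excluded;
with a continuous response this is a measure-zero event.

### DHGLM: double hierarchical generalized linear model

The mean part above is coupled with a variance part: the per-record log
residual variance gets its own linear predictor with the same factor
structure, additive genetic effects $\mathbf{a}_v$ and permanent
environment $\mathbf{pe}_v$, with

$$\begin{pmatrix}\mathbf{a}\\ \mathbf{a}_v\end{pmatrix} \sim
N\!\left(\mathbf{0}, \begin{pmatrix}\sigma^2_a & \sigma_{a,av}\\
\sigma_{a,av} & \sigma^2_{av}\end{pmatrix} \otimes \mathbf{A}\right),
\qquad
\begin{pmatrix}\mathbf{pe}\\ \mathbf{pe}_v\end{pmatrix} \sim
N\!\left(\mathbf{0}, \begin{pmatrix}\sigma^2_{pe} & \sigma_{pe,pev}\\
\sigma_{pe,pev} & \sigma^2_{pev}\end{pmatrix} \otimes \mathbf{I}\right).$$

The two parts are fitted jointly as a stacked weighted linear mixed model
and iterated: after each cycle the mean-part residual weights become
$\mathbf{W} = \mathrm{diag}(\exp(\hat\psi))^{-1}$ (reciprocals of the
predicted residual variances) and the variance-part weights
$\mathbf{W}_v = \mathrm{diag}((1-h)/2)$, where $h$ is the hat-diagonal
leverage of the mean-part records. The residual scaling variances
$\sigma^2_e$ and $\sigma^2_{ev}$ of the two parts are expected to be close
to 1 at convergence.

**Working response.** The variance part needs a response that carries the
information in the squared residuals. Fitting $\log(e^2/(1-h))$ directly
is attractive but has two defects: its mean is offset by
$E[\log\chi^2_1] \approx -1.27$, which a linear fit absorbs into the
intercept and which then propagates into the weights (the mean-part
scaling variance converges to $\approx e^{1.27} \approx 3.6$ instead of
1), and single extreme residuals can destabilise the iteration. We
therefore use the standard gamma-GLM linearisation around the current
predictor,

$$\psi_i = \hat\psi_i + \frac{e_i^2/(1-h_i) - \exp(\hat\psi_i)}
{\exp(\hat\psi_i)},$$

which is iteratively equivalent (same fixed point in the variance-part
effects) and makes the scaling variances interpretable. The initial cycle
starts from a flat predictor $\hat\psi \equiv \log\hat\sigma^2_e$ of the
converged mean model.

**Numerical safeguards.** The standardized squared residual
$e^2/((1-h)\exp(\hat\psi))$ is trimmed at 36 (a six-sigma event under the
model) before entering the working response; the variance-part linear
predictor is clamped to $[-10, 15]$ on the log scale; squared residuals
are floored at $10^{-12}$. From the fourth cycle on the new linear
predictor is relaxed towards the previous one with factor 0.5, which
suppresses a small odd/even oscillation of the weight/response feedback
without changing the fixed point. The inner REML is warm-started and
iteration-capped per cycle; the caps default to 30 (first cycle) and 10
(later cycles) L-BFGS-B iterations — starving the inner optimisation much
below that lets small herds drift into a degenerate basin in which the
permanent-environment variance collapses. The iteration stops when every
variance component changes by less than `tol` (relative; default
$5 \times 10^{-3}$) and
successive variance-part EBV correlate above $1-10^{-6}$. With the
iteration-capped inner REML the practical resolution of the outer loop is
of the order of 0.1–1% in the components; demanding much tighter
tolerances only burns cycles inside the optimizer's noise floor.

**What the scaling variances can and cannot show.** The mean-part scaling
variance $\sigma^2_e$ converges to 1 (checked by the test suite). The
variance-part scaling $\sigma^2_{ev}$ converges to roughly the average of
$(1-h)$: the $2/(1-h)$ variance ascribed to the working response by the
weight formula is an upper bound that becomes exact only as leverages
vanish. On datasets of the size used in the tests (mean leverage 0.2–0.3)
$\sigma^2_{ev}$ settles around 0.7–0.9; on production-scale data (hundreds
of thousands of records, small leverages) it approaches 1.

### REML engine

All fits go through one sparse engine: Henderson's mixed-model equations
with $\mathbf{A}^{-1}$ from Henderson's rules (Meuwissen–Luo inbreeding),
restricted log-likelihood evaluated through the sparse Cholesky
factorisation of the coefficient matrix, and direct maximisation over a
log / log-Cholesky parametrisation (L-BFGS-B with a cached
forward-difference gradient). This keeps every variance and every 2x2
covariance matrix positive (semi)definite by construction; boundary
estimates appear as log-parameters at the box bound ($e^{-12}$ of the data
scale, effectively zero). Likelihood equality with a dense GLS oracle is
part of the test suite, as are PEV (prediction error variances, from the
inverse coefficient matrix) and hat leverages against dense computations.
Component standard errors come from the numerical observed information on
the transformed scale, delta-methoded to variances and correlations.

An average-information update with expectation-maximisation fallback
would be the classical alternative; direct maximisation was chosen
because it shares one code path between the univariate, grouped-residual
and bivariate models and is easier to make robust at bounds.

### Evaluation machinery

* **Theoretical accuracy** $r = \sqrt{1 - \mathrm{PEV}/\sigma^2_a}$.
* **Deregression** removes the parent-average part of an EBV by solving
  the two-equation information-splitting system for the (parent average,
  individual) pair; for animals with both parents unknown this reduces to
  the classical $\mathrm{EBV}/r^2$. The weight constant $c$ (fraction of
  genetic variance not captured by markers) defaults to 0.5 and only
  enters the emitted weights; the association scan uses unweighted
  deregressed EBV, matching common mixed-linear-model GWAS practice.
* **Cross-validation** masks one daughter per paternal half-sib family
  (families with at least three recorded daughters; disjoint folds),
  refits both tracks on the training records and correlates predicted
  variability EBV of masked sows with their realized log-variance of
  litter size. Methods are compared with a paired one-sided t-test across
  folds (the fold correlations share the masked-animal structure, so the
  paired version is the conservative natural choice; the alternative
  two-sample form is not reported).
* **GWAS** on deregressed EBV: genotype QC (call rate 0.95, MAF 0.01,
  Hardy-Weinberg $\chi^2 \le 600$, autosomal mapped SNPs, animal
  missingness 0.05), VanRaden method-1 GRM, null-model REML through the
  GRM eigendecomposition, then per-SNP generalized least squares with the
  null variance ratio held fixed (the standard approximation for scans;
  exact per-SNP REML changes nothing at these effect sizes but costs a
  factor of hundreds). Significant: $p < 10^{-6}$; suggestive:
  $p < 10^{-4}$ and LD $r^2 \ge 0.2$ with a significant SNP (the LD
  requirement has no published cutoff; 0.2 is the conventional "some LD"
  line and is configurable). Regions merge when they share members; the
  index SNP is the member with the smallest p-value. The inflation factor
  is the median association $\chi^2$ over 0.4549.

## The simulator

`sim_config()` encodes the study conditions: a multi-generation half-sib
pedigree (default 25 sires x 20 dams each per generation, 3 generations),
2–10 litters per sow, mean TNB 13.76, additive variance 1.33 and permanent
environment 0.86 for the mean part, base residual variance 7.67
($\eta = \log 7.67$), variance-part additive variance 0.037 and permanent
environment 0.15, genetic correlation 0.43 and permanent-environment
correlation -0.87. Records follow the exponential model
$y = \mu + \mathrm{fixed} + u + pe + \exp(\tfrac12(\eta + v + pe_v))\,
\varepsilon$. Breeding values propagate by parent average plus Mendelian
sampling scaled by $\tfrac12(1 - (F_s + F_d)/2)$, consistent with the
$\mathbf{A}$ matrix used in fitting. Fixed effects exist so that they are
estimable but their values are free: parity effects default to a concave
parity curve, herd-year-season effects are drawn once per level from
$N(0, 0.5^2)$.

Genotypes come from gene dropping: founder haplotypes with allele
frequencies from `maf_range` and linkage disequilibrium induced by a
latent AR(1) Gaussian field (decaying LD with distance), descendants by
per-adjacent-pair Bernoulli recombination without interference. A causal
SNP can be planted into the variance part (`causal_snp`). The phenotype is
continuous by default; integer rounding/clamping is available but off,
because the fitted models are Gaussian and the effect of TNB discreteness
on the variance part is an open question better explored than hard-coded.

What the simulator does **not** emulate: selection over generations,
genotyping error, real pig linkage maps, non-Gaussian litter-size tails.
Parameter-recovery tests on these data therefore show the estimators are
consistent with their own assumptions at desk scale, not that real TNB
data satisfy those assumptions.

## Problem sizes in the test suite

The checks run at deliberately reduced scale so the whole suite stays
interactive: variance-component recovery on ~1,000 sows (three
generations, ~6,000 records), DHGLM recovery and null runs on the same
herd size, cross-validation on ~360 sows, and the association power study
on 3,000 genotyped animals with 2,000 SNPs and 20 replicates. At these
sizes the component standard errors are a few times larger than in a
production population, which the 2-SE acceptance bands account for;
point-size-dependent quantities (the variance-part scaling variance, the
absolute null floor for $\sigma^2_{av}$) are discussed above and in the
test files.

## Known limitations

* The variance-part additive variance is the hardest parameter in the
  model: at a thousand sows its REML surface is flat over a decade, and
  point estimates scatter accordingly (the correlations are much better
  determined). Production-scale data are needed for tight estimates, as
  the original analyses of this design used.
* The DHGLM inner REML is iteration-capped per cycle; the outer/inner
  interplay resolves components to ~0.1–1%, not machine precision.
* Deregression assumes the parent-average reliability is available from
  the same evaluation; external EBV sources are not supported.
* No genomic BLUP / single-step evaluation, no maternal or dominance
  effects, no imputation.
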