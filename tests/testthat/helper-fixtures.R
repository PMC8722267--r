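# Shared fixtures for the test suite. Everything is generated in code so
# tests stay self-contained and seeded.

# trio: unrelated sire and dam, one offspring
trio_pedigree <- function() {
  pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
}

# small pedigree of unrelated founder sows (for founder-only oracles)
founder_pedigree <- function(n) {
  pedigree(sprintf("F%03d", seq_len(n)), rep("0", n), rep("0", n),
           sex = rep("F", n))
}

# default small simulation used across tests (~540 sows)
small_sim <- function(seed = 5, ...) {
  cfg <- sim_config(n_sires = 15, n_dams_per_sire = 12, n_generations = 3,
                    seed = seed, ...)
  simulate_dataset(cfg)
}

# toy litter records with known editing outcomes
toy_records <- function() {
  data.frame(
    sow = c("a", "a", "a", "b", "b", "c", "c", "d", "d", "d"),
    parity = c(1, 2, 12, 1, 2, 1, 2, 1, 2, 3),
    hys = rep("h1", 10),
    tnb = c(12, 27, 14, 3, 13, 2, 3, 10, 11, 12),
    stringsAsFactors = FALSE
  )
}

# dense GLS/BLUP oracle for a model with one additive term (pedigree A),
# optional permanent-environment term and diagonal residual
dense_blup_oracle <- function(y, X, Zs, A, var_a, var_pe = NULL, Zpe = NULL,
                              rvar = rep(1, length(y))) {
  V <- Zs %*% (var_a * A) %*% t(Zs) + diag(rvar, length(y))
  if (!is.null(var_pe)) V <- V + var_pe * tcrossprod(Zpe)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  resid0 <- y - X %*% beta
  u <- var_a * A %*% t(Zs) %*% Vi %*% resid0
  pe <- if (!is.null(var_pe)) var_pe * t(Zpe) %*% Vi %*% resid0 else NULL
  list(beta = as.numeric(beta), u = as.numeric(u),
       pe = if (!is.null(pe)) as.numeric(pe) else NULL)
}
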