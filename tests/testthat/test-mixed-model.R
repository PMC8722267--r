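test_that("MME solutions equal the dense GLS oracle on random small models", {
  set.seed(77)
  for (rep in 1:8) {
    n_anim <- sample(6:10, 1)
    n_founder <- 4
    sire <- dam <- integer(n_anim)
    for (i in (n_founder + 1):n_anim) {
      sire[i] <- sample(i - 1, 1)
      dam[i] <- sample(max(1, i - 2), 1)
      if (dam[i] == sire[i]) dam[i] <- 0
    }
    ped <- pedigree(1:n_anim, sire, dam)
    ids <- as.character(seq_len(n_anim))
    n_rec <- sample(15:30, 1)
    dat <- data.frame(
      sow = sample(ids, n_rec, replace = TRUE),
      parity = sample(1:3, n_rec, replace = TRUE),
      hys = sample(c("h1", "h2"), n_rec, replace = TRUE),
      tnb = rnorm(n_rec, 12, 2)
    )
    # ensure estimable design
    dat$hys[1:2] <- c("h1", "h2"); dat$parity[1:3] <- 1:3
    va <- runif(1, 0.5, 2); vpe <- runif(1, 0.2, 1); ve <- runif(1, 1, 4)
    use_pe <- rep == 1 || runif(1) > 0.3
    fit <- fit_animal_model(dat, "tnb", fixed = c("hys", "parity"), ped = ped,
                            animal = "sow",
                            permanent_env = if (use_pe) "sow" else NULL,
                            start = list(var_a = va, var_pe = vpe, var_e = ve),
                            reml = FALSE)
    A <- a_matrix(ped)
    X <- littervar:::mm_fixed_design(dat, c("hys", "parity"), n_rec)
    Zs <- matrix(0, n_rec, n_anim)
    Zs[cbind(seq_len(n_rec), match(dat$sow, ids))] <- 1
    fpe <- factor(dat$sow)
    Zpe <- matrix(0, n_rec, nlevels(fpe))
    Zpe[cbind(seq_len(n_rec), as.integer(fpe))] <- 1
    orc <- dense_blup_oracle(dat$tnb, X, Zs, A, va,
                             var_pe = if (use_pe) vpe else NULL,
                             Zpe = Zpe, rvar = rep(ve, n_rec))
    expect_equal(unname(fit$beta), orc$beta, tolerance = 1e-8)
    expect_equal(unname(fit$ebv), orc$u, tolerance = 1e-8)
    if (use_pe) {
      expect_equal(unname(fit$pe[levels(fpe)]), orc$pe, tolerance = 1e-8)
    }
  }
})

test_that("weighted and grouped residuals match the dense oracle", {
  set.seed(101)
  ped <- founder_pedigree(8)
  ids <- attr(ped, "labels")
  n <- 24
  dat <- data.frame(sow = rep(ids, 3), parity = rep(1:3, each = 8),
                    hys = "h1", tnb = rnorm(n, 10, 2),
                    grp = rep(c("g1", "g2"), 12))
  w <- runif(n, 0.5, 2)
  ve <- c(g1 = 2.5, g2 = 1.1)
  fit <- fit_animal_model(dat, "tnb", fixed = "parity", ped = ped,
                          animal = "sow", resid_group = "grp", weights = w,
                          start = list(var_a = 1.3, var_e = ve),
                          reml = FALSE)
  A <- diag(8)
  X <- littervar:::mm_fixed_design(dat, "parity", n)
  Zs <- matrix(0, n, 8); Zs[cbind(1:n, match(dat$sow, ids))] <- 1
  rvar <- ve[dat$grp] / w
  orc <- dense_blup_oracle(dat$tnb, X, Zs, A, 1.3, rvar = rvar)
  expect_equal(unname(fit$ebv), orc$u, tolerance = 1e-8)
  expect_equal(unname(fit$beta), orc$beta, tolerance = 1e-8)
})

test_that("PEV and leverage match the dense MME inverse", {
  set.seed(55)
  ped <- trio_pedigree()
  dat <- data.frame(sow = c("S", "S", "D", "D", "O", "O"),
                    parity = rep(1:2, 3), hys = "h",
                    tnb = rnorm(6, 12, 1.5))
  va <- 1.2; ve <- 2.0
  fit <- fit_animal_model(dat, "tnb", fixed = NULL, ped = ped,
                          animal = "sow",
                          start = list(var_a = va, var_e = ve), reml = FALSE)
  X <- matrix(1, 6, 1)
  Z <- matrix(0, 6, 3); Z[cbind(1:6, rep(1:3, each = 2))] <- 1
  W <- cbind(X, Z)
  Ainv <- solve(a_matrix(ped))
  C <- t(W) %*% W / ve
  C[2:4, 2:4] <- C[2:4, 2:4] + Ainv / va
  Ci <- solve(C)
  expect_equal(unname(fit$pev), diag(Ci)[2:4], tolerance = 1e-8)
  H <- W %*% Ci %*% t(W) / ve
  expect_equal(fit$leverage, diag(H), tolerance = 1e-8)
  # leverage sums to the trace of the hat projection, and lies in [0, 1)
  expect_equal(sum(fit$leverage), sum(diag(H)), tolerance = 1e-8)
  expect_true(all(fit$leverage >= 0 & fit$leverage < 1))
  # PEV bounded by the additive variance times the diagonal of A
  expect_true(all(fit$pev <= va * diag(a_matrix(ped)) + 1e-10))
})

test_that("model with no random-term signal collapses to least squares", {
  set.seed(66)
  ped <- founder_pedigree(5)
  dat <- data.frame(sow = rep(attr(ped, "labels"), each = 4),
                    parity = rep(1:4, 5),
                    hys = sample(c("h1", "h2"), 20, replace = TRUE),
                    tnb = rnorm(20, 11, 1))
  fit <- fit_animal_model(dat, "tnb", fixed = c("hys", "parity"), ped = ped,
                          animal = "sow",
                          start = list(var_a = 1e-9, var_e = 1),
                          reml = FALSE)
  ols <- lm(tnb ~ hys + factor(parity), dat)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-5)
})

test_that("REML recovers known variance components (moderate simulation)", {
  cfg <- sim_config(n_sires = 25, n_dams_per_sire = 14, n_generations = 3,
                    var_av = 0, var_pev = 0, r_a_av = 0, r_pe_pev = 0,
                    seed = 42)
  sim <- simulate_dataset(cfg)
  rec <- apply_edit_rules(sim$records)
  fit <- fit_animal_model(rec, "tnb", fixed = c("hys", "parity"),
                          ped = sim$ped, animal = "sow",
                          permanent_env = "sow", se = TRUE,
                          compute_pev = FALSE, compute_leverage = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$vc$var_a - 1.33), 2 * fit$vc$se$var_a)
  expect_lt(abs(fit$vc$var_pe - 0.86), 2 * fit$vc$se$var_pe)
  expect_lt(abs(fit$vc$var_e - 7.67), 2 * fit$vc$se$var_e)
})

test_that("heritability ratios match the printed closed forms", {
  expect_equal(round(heritability(1.33, 7.67, var_pe = 0.86), 3), 0.135)
  expect_equal(round(heritability(0.033, 1.33), 3), 0.024)
  expect_equal(heritability(0, 5), 0)
  # grouped residuals use the record-weighted mean
  expect_equal(heritability(1, c(2, 4), resid_weights = c(3, 1)),
               1 / (1 + 2.5))
  expect_error(heritability(0, 0), "positive")
})

test_that("aliased fixed-effect levels are reported, not fatal", {
  set.seed(5)
  ped <- founder_pedigree(4)
  dat <- data.frame(sow = rep(attr(ped, "labels"), 3),
                    parity = 1, hys = rep(c("h1", "h2"), 6),
                    dup = rep(c("h1", "h2"), 6),
                    tnb = rnorm(12, 10))
  fit <- fit_animal_model(dat, "tnb", fixed = c("hys", "dup"), ped = ped,
                          animal = "sow",
                          start = list(var_a = 1, var_e = 1), reml = FALSE)
  expect_gt(length(fit$aliased), 0)
})
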