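# Small DHGLM fixtures: a compact simulated herd so individual update
# cycles stay cheap; parameter recovery at scale is exercised in the
# acceptance suite.

dhglm_fixture <- function(seed = 61, ...) {
  cfg <- sim_config(n_sires = 8, n_dams_per_sire = 10, n_generations = 2,
                    seed = seed, ...)
  sim <- simulate_dataset(cfg)
  list(sim = sim, rec = apply_edit_rules(sim$records))
}

test_that("initialization builds the working response and weights", {
  fx <- dhglm_fixture()
  fit <- fit_animal_model(fx$rec, "tnb", fixed = c("hys", "parity"),
                          ped = fx$sim$ped, animal = "sow",
                          permanent_env = "sow", compute_pev = FALSE)
  st <- initialize_dhglm(fit)
  # working response at the flat start log(sigma2_e): hand-check
  ve <- fit$vc$var_e[1]
  i <- which.max(abs(fit$residuals))
  expect_equal(st$psi[i],
               log(ve) + fit$residuals[i]^2 /
                 ((1 - fit$leverage[i]) * ve) - 1)
  # variance-part weights (1 - h) / 2; h = 0.5 gives 0.25
  expect_equal(st$Wv, (1 - pmin(pmax(fit$leverage, 0), 1 - 1e-8)) / 2)
  expect_equal((1 - 0.5) / 2, 0.25)
  # homoscedastic start: all mean-part weights equal 1 / sigma2_e
  expect_equal(unique(st$W), 1 / fit$vc$var_e[1])
  expect_equal(st$s2e, 1)
})

test_that("one update refreshes weights as exp(-psi_hat)", {
  fx <- dhglm_fixture()
  fit <- fit_animal_model(fx$rec, "tnb", fixed = c("hys", "parity"),
                          ped = fx$sim$ped, animal = "sow",
                          permanent_env = "sow", compute_pev = FALSE)
  st <- initialize_dhglm(fit)
  sys <- littervar:::dhglm_system(fx$rec, fx$sim$ped)
  st1 <- dhglm_update(st, sys, reml_maxit = 10)
  expect_equal(st1$W, exp(-st1$psi_hat))
  expect_equal(st1$Wv, (1 - st1$h) / 2)
  expect_true(all(st1$W > 0) && all(st1$Wv > 0))
  expect_true(all(is.finite(st1$psi)))
  # both 2x2 covariance matrices stay positive definite
  expect_gt(det(st1$Ga), 0)
  expect_gt(det(st1$Gpe), 0)
})

test_that("DHGLM is deterministic given the data", {
  fx <- dhglm_fixture()
  d1 <- suppressWarnings(run_dhglm(fx$rec, fx$sim$ped, max_iter = 4))
  d2 <- suppressWarnings(run_dhglm(fx$rec, fx$sim$ped, max_iter = 4))
  expect_identical(d1$Ga, d2$Ga)
  expect_identical(d1$ebv, d2$ebv)
})

test_that("a converged state is (numerically) a fixed point of the update", {
  fx <- dhglm_fixture(seed = 62)
  dh <- suppressWarnings(run_dhglm(fx$rec, fx$sim$ped, max_iter = 25,
                                   tol = 5e-3))
  sys <- littervar:::dhglm_system(fx$rec, fx$sim$ped)
  # rebuild the converged state and apply one more update: the variance
  # components should barely move
  st <- structure(list(iter = dh$iterations, psi = dh$psi_work,
                       W = dh$W, Wv = dh$Wv, h = dh$leverage,
                       Ga = dh$Ga, Gpe = dh$Gpe,
                       s2e = dh$s2e, s2ev = dh$s2ev, trace = list()),
                  class = "lv_dhglm_state")
  st1 <- dhglm_update(st, sys, reml_maxit = 5)
  v0 <- littervar:::dhglm_vc_vec(st)
  v1 <- littervar:::dhglm_vc_vec(st1)
  # judge stability on the well-determined components; tiny covariances
  # have exploding relative changes on a herd this small
  big <- abs(v0) > 0.05
  expect_lt(max(abs(v1[big] - v0[big]) / abs(v0[big])), 0.1)
})

test_that("under null variance genetics sigma2_av shrinks toward zero", {
  fx <- dhglm_fixture(seed = 63, var_av = 0, var_pev = 0,
                      r_a_av = 0, r_pe_pev = 0)
  dh <- suppressWarnings(run_dhglm(fx$rec, fx$sim$ped, max_iter = 10))
  # across the recorded trajectory, var_av never grows over cycles by much
  av <- vapply(dh$trace, `[[`, numeric(1), "ga22")
  expect_lt(av[length(av)], 0.05)
  # predicted residual variances average to the homoscedastic estimate
  expect_equal(mean(exp(dh$psi_hat)), dh$mean_fit_vc$var_e[1],
               tolerance = 0.15)
})

test_that("GCV on the SD level follows 0.5 * sqrt(variance)", {
  expect_equal(round(100 * gcv_sde(0.033), 1), 9.1)
  expect_equal(round(100 * gcv_sde(0.037), 1), 9.6)
  expect_equal(gcv_sde(0), 0)
  expect_error(gcv_sde(-0.1), ">= 0")
})
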