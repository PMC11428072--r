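sp2 <- msm_spec(states = c("well", "dead"), transitions = matrix(c(1L, 2L), 1),
                death = "dead")

test_that("panel likelihood matches closed forms on the 2-state chain", {
  # same-state panel pair over 1 year: log P11(1) = -q
  obs <- data.frame(patient_id = 1, time = c(0, 1), state = "well",
                    kind = "panel")
  expect_equal(panel_loglik(log(0.5), obs, spec = sp2), -0.5)

  # exactly observed death: log(P11(1) q) = -q + log q
  obs_d <- data.frame(patient_id = 1, time = c(0, 1),
                      state = c("well", "dead"),
                      kind = c("panel", "exact_death"))
  expect_equal(panel_loglik(log(0.5), obs_d, spec = sp2), -0.5 + log(0.5))

  # censoring over the full state set is probability 1 (loglik 0 term)
  obs_c <- data.frame(patient_id = 1, time = c(0, 1),
                      state = c("well", "well"),
                      kind = c("panel", "censored"),
                      censor_set = c(NA, "well|dead"))
  expect_equal(panel_loglik(log(0.5), obs_c, spec = sp2), 0)

  # empty observation set
  expect_equal(panel_loglik(log(0.5), obs[0, ], spec = sp2), 0)
})

test_that("compiled likelihood and gradient match the expm oracle", {
  set.seed(402)
  coh <- simulate_panel_cohort(sim_config(n_patients = 80, seed = 77))
  sp <- msm_spec()
  for (rep in 1:3) {
    th <- log(default_true_rates()) + stats::rnorm(8, 0, 0.3)
    expect_equal(panel_loglik(th, coh$observations, spec = sp),
                 oracle_loglik(th, coh$observations, sp),
                 tolerance = 1e-10)
  }
  # analytic gradient vs central differences
  prep <- dmpath:::prepare_msm_data(coh$observations, NULL, sp)
  th <- log(default_true_rates()) + stats::rnorm(8, 0, 0.2)
  g <- dmpath:::msm_loglik_cpp(th, prep, want_grad = TRUE)$grad
  gn <- vapply(seq_along(th), function(i) {
    h <- 1e-6; e1 <- e2 <- th; e1[i] <- e1[i] + h; e2[i] <- e2[i] - h
    (dmpath:::msm_loglik_cpp(e1, prep)$loglik -
       dmpath:::msm_loglik_cpp(e2, prep)$loglik) / (2 * h)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("likelihood with covariates matches a per-profile expm oracle", {
  set.seed(403)
  cfg <- sim_config(n_patients = 60, seed = 31,
                    betas = list("DM->Micro" = c(x = log(1.5))))
  coh <- simulate_panel_cohort(cfg)
  sp <- msm_spec(covariates = list("DM->Micro" = "x"))
  th <- c(log(default_true_rates()) + stats::rnorm(8, 0, 0.2), 0.4)
  ll <- panel_loglik(th, coh$observations, coh$covariates, sp)
  # oracle: split patients by covariate value, apply the covariate-free
  # oracle with the appropriately scaled DM->Micro rate
  ll_or <- 0
  for (xv in unique(coh$covariates$x)) {
    ids <- coh$covariates$patient_id[coh$covariates$x == xv]
    rates <- exp(th[1:8]); names(rates) <- sp$labels
    rates["DM->Micro"] <- rates["DM->Micro"] * exp(th[9] * xv)
    Q <- build_generator(rates, spec = msm_spec())
    ob <- coh$observations[coh$observations$patient_id %in% ids, ]
    ll_or <- ll_or + oracle_loglik(NULL, ob, msm_spec(), Q = Q)
  }
  expect_equal(ll, ll_or, tolerance = 1e-10)
  # gradient including the beta parameter
  prep <- dmpath:::prepare_msm_data(coh$observations, coh$covariates, sp)
  g <- dmpath:::msm_loglik_cpp(th, prep, want_grad = TRUE)$grad
  gn <- vapply(seq_along(th), function(i) {
    h <- 1e-6; e1 <- e2 <- th; e1[i] <- e1[i] + h; e2[i] <- e2[i] - h
    (dmpath:::msm_loglik_cpp(e1, prep)$loglik -
       dmpath:::msm_loglik_cpp(e2, prep)$loglik) / (2 * h)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("impossible observed pairs give -Inf, and fit refuses them", {
  obs <- data.frame(patient_id = 1, time = c(0, 1),
                    state = c("Micro", "DM"), kind = "panel")
  expect_identical(panel_loglik(log(default_true_rates()), obs), -Inf)
  expect_error(msm_fit(obs), "impossible")
  # Micro -> Macro is forward in index order but unreachable in the DAG
  obs2 <- data.frame(patient_id = 1, time = c(0, 1),
                     state = c("Micro", "Macro"), kind = "panel")
  expect_identical(panel_loglik(log(default_true_rates()), obs2), -Inf)
})

test_that("time-varying covariates are carried forward per interval", {
  sp <- msm_spec(covariates = list("DM->Micro" = "x"))
  th <- c(log(default_true_rates()), 0.7)
  obs <- data.frame(patient_id = "A", time = c(0, 1, 2),
                    state = c("DM", "DM", "Micro"), kind = "panel")
  # x switches from 0 to 1 at t = 1
  cov_tv <- data.frame(patient_id = "A", time = c(0, 1), x = c(0, 1))
  ll <- panel_loglik(th, obs, cov_tv, sp)
  rates0 <- exp(th[1:8]); names(rates0) <- msm_spec()$labels
  rates1 <- rates0; rates1["DM->Micro"] <- rates1["DM->Micro"] * exp(th[9])
  P0 <- as.matrix(Matrix::expm(build_generator(rates0) * 1))
  P1 <- as.matrix(Matrix::expm(build_generator(rates1) * 1))
  expect_equal(ll, log(P0["DM", "DM"]) + log(P1["DM", "Micro"]),
               tolerance = 1e-10)
  # constant time-varying rows reduce to the baseline-covariate fit
  cov_const <- data.frame(patient_id = "A", time = c(0, 1), x = c(1, 1))
  cov_base <- data.frame(patient_id = "A", x = 1)
  expect_equal(panel_loglik(th, obs, cov_const, sp),
               panel_loglik(th, obs, cov_base, sp), tolerance = 1e-12)
})
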