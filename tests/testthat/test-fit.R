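test_that("one-parameter MLE matches a fine grid search", {
  sp2 <- msm_spec(states = c("well", "dead"), transitions = matrix(c(1L, 2L), 1),
                  death = "dead")
  set.seed(404)
  n <- 150
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    td <- stats::rexp(1, 0.3)
    if (td < 2) data.frame(patient_id = i, time = c(0, td),
                           state = c("well", "dead"),
                           kind = c("panel", "exact_death"),
                           censor_set = NA)
    else data.frame(patient_id = i, time = c(0, 2), state = "well",
                    kind = c("panel", "censored"), censor_set = c(NA, "well"))
  }))
  fit <- msm_fit(obs, spec = sp2)
  grid <- seq(log(0.05), log(1.5), length.out = 4001)
  ll <- vapply(grid, function(g) panel_loglik(g, obs, spec = sp2), numeric(1))
  expect_equal(unname(fit$par), grid[which.max(ll)], tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$AIC, -2 * fit$loglik + 2, tolerance = 1e-12)
})

test_that("simulation consistency: MLEs near truth, HR CI sane", {
  coh <- simulate_panel_cohort(sim_config(n_patients = 1200, seed = 405))
  fit <- msm_fit(coh$observations)
  expect_true(fit$converged)
  ci <- baseline_intensities(fit)
  truth <- default_true_rates()
  se_log <- sqrt(diag(fit$vcov)[1:8])
  # all estimates within 3 SEs of truth on the log scale (forward
  # transitions are well identified at this size; death rates noisier)
  zdev <- abs(log(ci[, "rate"]) - log(truth)) / se_log
  expect_true(all(zdev[c(1, 2, 4, 6)] < 3))
  expect_true(all(ci[, "lower"] <= ci[, "upper"]))

  # likelihood at the truth beats +/- 50% perturbations of all rates
  th0 <- log(truth)
  ll0 <- panel_loglik(th0, coh$observations)
  expect_gt(ll0, panel_loglik(th0 + log(1.5), coh$observations))
  expect_gt(ll0, panel_loglik(th0 + log(0.5), coh$observations))
})

test_that("hazard ratios are exp(beta) with ordered Wald intervals", {
  cfg <- sim_config(n_patients = 800, seed = 406,
                    betas = list("DM->Micro" = c(x = log(1.5))))
  coh <- simulate_panel_cohort(cfg)
  sp <- msm_spec(covariates = list("DM->Micro" = "x"))
  fit <- msm_fit(coh$observations, coh$covariates, sp)
  hr <- hazard_ratios(fit)
  expect_equal(nrow(hr), 1L)
  b <- fit$par[9]; se <- sqrt(fit$vcov[9, 9])
  expect_equal(hr$HR, unname(exp(b)))
  expect_equal(hr$lower, unname(exp(b - stats::qnorm(0.975) * se)))
  expect_equal(hr$upper, unname(exp(b + stats::qnorm(0.975) * se)))
  expect_true(hr$lower < hr$HR && hr$HR < hr$upper)
  # reporting style "HR = x.xxx [l.lll, u.uuu]" renders cleanly
  expect_match(sprintf("HR = %.3f [%.3f, %.3f]", hr$HR, hr$lower, hr$upper),
               "^HR = \\d+\\.\\d{3} \\[\\d+\\.\\d{3}, \\d+\\.\\d{3}\\]$")
})

test_that("lrt: zero statistic on identical fits, errors on non-nested order", {
  coh <- simulate_panel_cohort(sim_config(n_patients = 150, seed = 407))
  fit <- msm_fit(coh$observations)
  out <- lrt(fit, fit)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 0)
  expect_equal(out$p.value, 1)
})

test_that("pmatrix and its parametric bootstrap behave", {
  coh <- simulate_panel_cohort(sim_config(n_patients = 600, seed = 408))
  fit <- msm_fit(coh$observations)
  P <- pmatrix(fit, 1)
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-10)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(P["DM", "Both"]) > 0, TRUE)  # reachable in two jumps
  expect_equal(unname(P["Micro", "Macro"]), 0, tolerance = 1e-12)

  ci <- pmatrix_ci(fit, 1, B = 200, seed = 1)
  expect_true(all(ci$lower <= ci$point + 1e-12 & ci$point <= ci$upper + 1e-12))
  # B = 1 collapses to a degenerate interval
  ci1 <- pmatrix_ci(fit, 1, B = 1, seed = 2)
  expect_equal(ci1$lower, ci1$upper)
})

test_that("print/summary/coef/logLik methods expose the fit", {
  coh <- simulate_panel_cohort(sim_config(n_patients = 100, seed = 409))
  fit <- msm_fit(coh$observations)
  expect_named(coef(fit))
  expect_equal(length(coef(fit)), 8L)
  expect_s3_class(summary(fit), "summary.dmpath_fit")
  expect_output(print(fit), "Progressive multistate model fit")
  ll <- logLik(fit)
  expect_equal(AIC(ll), fit$AIC)
  expect_equal(dim(vcov(fit)), c(8L, 8L))
})
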