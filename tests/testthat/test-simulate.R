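test_that("trajectory simulation: degenerate and closed-form cases", {
  sp <- msm_spec()
  # all intensities zero: patient stays in DM for the whole horizon
  Q0 <- build_generator(stats::setNames(rep(0, 8), sp$labels), spec = sp)
  tr <- simulate_trajectory(Q0, 5)
  expect_identical(tr$state, "DM")
  expect_equal(tr$end_time, 5)
  expect_identical(tr$status, "censored")

  # absorbing start state: trivial trajectory
  tr2 <- simulate_trajectory(Q0, 5, start = 5L)
  expect_identical(tr2$state, "Death")

  # 2-state chain, q = 0.5: mean exit time 1/q = 2
  sp2 <- msm_spec(states = c("a", "b"), transitions = matrix(c(1L, 2L), 1),
                  death = NULL)
  Q <- build_generator(c("a->b" = 0.5), spec = sp2)
  set.seed(410)
  exits <- replicate(10000, simulate_trajectory(Q, Inf)$end_time)
  se <- 2 / sqrt(10000)  # exponential: sd = mean
  expect_lt(abs(mean(exits) - 2), 3 * se)
})

test_that("empirical state distribution matches expm(Q) at t = 1", {
  set.seed(411)
  rates <- default_true_rates()
  Q <- build_generator(rates)
  n <- 20000
  at1 <- character(n)
  for (i in seq_len(n)) {
    tr <- simulate_trajectory(Q, 1)
    at1[i] <- tr$state[length(tr$state)]
  }
  emp <- table(factor(at1, levels = dm_states())) / n
  theo <- transition_probability(Q, 1)["DM", ]
  for (s in dm_states()) {
    se <- sqrt(theo[s] * (1 - theo[s]) / n)
    expect_lt(abs(emp[[s]] - theo[[s]]), 3 * se + 1e-12)
  }
  # chi-square goodness of fit not rejected at alpha = 0.01
  gof <- suppressWarnings(stats::chisq.test(table(factor(at1, levels = dm_states())),
                                            p = theo))
  expect_gt(gof$p.value, 0.01)
})

test_that("generated trajectories respect the forward-only partial order", {
  set.seed(412)
  coh <- simulate_panel_cohort(sim_config(n_patients = 300, seed = 413))
  ord <- c(DM = 1, Micro = 2, Macro = 2, Both = 3, Death = 4)
  tr <- coh$truth$trajectories
  for (p in unique(tr$patient_id)) {
    s <- tr$state[tr$patient_id == p]
    expect_true(all(diff(ord[s]) > 0))
    # no DM -> Both jump
    if (length(s) > 1)
      expect_false(any(s[-length(s)] == "DM" & s[-1] == "Both"))
  }
  # observation records are forward-only too
  ob <- coh$observations
  for (p in unique(ob$patient_id)[1:50]) {
    s <- ob$state[ob$patient_id == p & ob$kind == "panel"]
    expect_true(all(diff(ord[s]) >= 0))
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- simulate_panel_cohort(sim_config(n_patients = 100, seed = 99))
  b <- simulate_panel_cohort(sim_config(n_patients = 100, seed = 99))
  expect_identical(a, b)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  ca <- generate_cohort(sim_config(n_patients = 40, seed = 7), dir = d1)
  cb <- generate_cohort(sim_config(n_patients = 40, seed = 7), dir = d2)
  expect_identical(ca$tables, cb$tables)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("cohort marginals and missingness match the configuration", {
  n <- 4000
  cfg <- sim_config(n_patients = n, seed = 414,
                    missingness = list(hba1c = 0.30))
  co <- generate_cohort(cfg)
  # female proportion near its 56.2% marginal
  pf <- mean(co$tables$patients$sex == "F")
  expect_lt(abs(pf - 0.562), 3 * sqrt(0.562 * 0.438 / n))
  # 30% MCAR missingness in baseline HbA1c
  fm <- mean(is.na(co$baseline$hba1c))
  expect_lt(abs(fm - 0.30), 3 * sqrt(0.3 * 0.7 / n))
  # truth sidecar round-trips through disk
  d <- file.path(tempdir(), "cohRT")
  co2 <- generate_cohort(sim_config(n_patients = 30, seed = 5), dir = d)
  back <- read_cohort(d)
  expect_equal(unlist(back$truth$rates), unlist(co2$truth$rates),
               tolerance = 1e-12)
  expect_equal(back$truth$seed, 5)
})

test_that("MAR missingness depends on age in the configured direction", {
  cfg <- sim_config(n_patients = 6000, seed = 415,
                    missingness = list(hba1c = list(p = 0.3, mechanism = "MAR")))
  co <- generate_cohort(cfg)
  miss <- is.na(co$baseline$hba1c)
  old <- co$baseline$age > stats::median(co$baseline$age)
  expect_gt(mean(miss[old]), mean(miss[!old]))
})
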