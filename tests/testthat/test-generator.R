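test_that("generator assembly obeys mask, row sums and covariate scaling", {
  sp <- msm_spec()
  rates <- stats::setNames(c(0.1334, 0.0508, 0.004, 0.0395, 0.002, 0.0784,
                             0.003, 0.013), sp$labels)
  Q <- build_generator(rates, spec = sp)
  expect_equal(rowSums(Q), stats::setNames(rep(0, 5), sp$states))
  mask <- attr(Q, "mask")
  offdiag <- row(Q) != col(Q)
  expect_true(all(Q[offdiag & !mask] == 0))
  expect_true(all(Q[mask] >= 0))
  expect_identical(unname(Q["Death", ]), rep(0, 5))
  # no covariates: Q equals the baseline intensities
  expect_equal(Q["DM", "Micro"], 0.1334)

  # beta = log 2 with z = 1 doubles exactly that intensity
  Q2 <- build_generator(rates, betas = list("DM->Micro" = c(x = log(2))),
                        z = c(x = 1), spec = sp)
  expect_equal(Q2["DM", "Micro"], 2 * 0.1334)
  expect_equal(Q2["DM", "Macro"], 0.0508)

  # an ADI-style HR of 1.365 multiplies the DM->Micro rate by 1.365
  Q3 <- build_generator(rates, betas = list("DM->Micro" = c(adi910 = log(1.365))),
                        z = c(adi910 = 1), spec = sp)
  expect_equal(Q3["DM", "Micro"], 0.1334 * 1.365, tolerance = 1e-12)

  # beta = 0 leaves the baseline untouched
  Q4 <- build_generator(rates, betas = list("DM->Micro" = c(x = 0)),
                        z = c(x = 3), spec = sp)
  expect_equal(unclass(Q4), unclass(Q), ignore_attr = TRUE)

  expect_error(build_generator(c("DM->Nowhere" = 1), spec = sp), "unknown transition")
  expect_error(build_generator(rates, betas = list("DM->Micro" = c(x = 710)),
                               z = c(x = 1), spec = sp), "non-finite")
})

test_that("transition probabilities: identity at 0, closed form for 2-state decay", {
  sp2 <- msm_spec(states = c("well", "dead"), transitions = matrix(c(1L, 2L), 1),
                  death = "dead")
  Q <- build_generator(c("well->dead" = 0.5), spec = sp2)
  expect_equal(transition_probability(Q, 0), diag(2), ignore_attr = TRUE)
  P <- transition_probability(Q, 1)
  expect_equal(P[1, 2], 1 - exp(-0.5), tolerance = 1e-12)
  expect_error(transition_probability(Q, -1), "nonnegative")
})

test_that("expm agrees with phase-type closed forms and Chapman-Kolmogorov", {
  set.seed(401)
  for (i in 1:25) {
    Q <- random_generator()
    t <- stats::runif(1, 0.2, 4)
    P <- transition_probability(Q, t)
    expect_equal(P, oracle_pmatrix(Q, t), tolerance = 1e-10)
    s <- stats::runif(1, 0.2, 4)
    expect_equal(transition_probability(Q, s + t),
                 transition_probability(Q, s) %*% transition_probability(Q, t),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("death-intensity calibration reproduces its probability targets", {
  rates <- calibrate_death_intensities(printed_forward_rates(),
                                       printed_death_probs())
  P <- transition_probability(build_generator(rates), 1)
  expect_equal(unname(P[1:4, "Death"]), printed_death_probs(), tolerance = 1e-9)
  # the Both row is pure exponential decay, so its death rate is closed form
  expect_equal(unname(rates["Both->Death"]), -log(1 - 0.013), tolerance = 1e-9)
})
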