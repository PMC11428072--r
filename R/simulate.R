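#' Simulate one trajectory of a continuous-time Markov chain
#'
#' Competing-exponential (Gillespie) sampling: the sojourn time in state
#' r is Exponential with the total exit rate, and the next state is
#' chosen with probability proportional to the off-diagonal intensities.
#' The trajectory is truncated at `horizon`.
#'
#' @param Q Generator matrix (e.g. from [build_generator()]).
#' @param horizon Follow-up horizon in years.
#' @param start Starting state index (default 1).
#' @return List with `time` and `state` (state-entry times, names from
#'   `Q`'s dimnames), `end_time`, and `status` (`"absorbed"` when an
#'   absorbing state was entered before `horizon`, else `"censored"`).
#' @export
simulate_trajectory <- function(Q, horizon, start = 1L) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  states <- rownames(Q)
  if (is.null(states)) states <- as.character(seq_len(n))
  t <- 0; s <- as.integer(start)
  times <- 0; path <- s
  repeat {
    total <- -Q[s, s]
    if (total <= 0) {  # current state is absorbing
      if (length(times) == 1L)
        return(list(time = times, state = states[path], end_time = horizon,
                    status = "censored"))
      return(list(time = times, state = states[path], end_time = t,
                  status = "absorbed"))
    }
    t <- t + stats::rexp(1, total)
    if (t >= horizon)
      return(list(time = times, state = states[path], end_time = horizon,
                  status = "censored"))
    rates <- Q[s, ]; rates[s] <- 0
    s <- sample.int(n, 1, prob = rates)
    times <- c(times, t); path <- c(path, s)
  }
}

#' Simulation configuration for a synthetic EHR cohort
#'
#' Collects the ground-truth parameters of the synthetic cohort
#' generator.  Defaults emulate the marginal structure of a primary-care
#' diabetes cohort: 56.2% female, 93.1% type 2 diabetes, mean age 54.7
#' (sd 14.1), 42.8% ever-smokers, baseline intensities equal to the
#' crude five-state intensities with death intensities calibrated to the
#' one-year death probabilities (see
#' [calibrate_death_intensities()]), about two ambulatory visits per
#' person-year, and lab/vital/ADI missingness in the ranges seen in raw
#' EHR extracts.
#'
#' @param n_patients Number of patients.
#' @param rates Named true baseline intensities per transition.
#' @param betas Named list of true per-transition log hazard ratios
#'   (names within each element are covariate names).
#' @param visit_rate Expected ambulatory visits per person-year
#'   (homogeneous Poisson process, plus a guaranteed index visit).
#' @param horizon Follow-up horizon in years: a single number, a
#'   function(n) returning per-patient horizons, or `NULL` (default)
#'   for per-patient Uniform(2, 7) follow-up, emulating staggered
#'   cohort entry over a five-year accrual window with two further
#'   years of follow-up (median 4.5 years).
#' @param p_female,p_type2,p_smoker Bernoulli marginals.
#' @param age_mean,age_sd Normal marginal for age at index.
#' @param covariate_dists Optional named list of additional covariate
#'   marginals, each `list(kind = "bernoulli", p = )`,
#'   `list(kind = "normal", mean = , sd = )`, or
#'   `list(kind = "categorical", probs = )` (named probabilities).
#' @param missingness Named list of per-variable missing fractions; each
#'   element either a number (MCAR) or `list(p = , mechanism = "MAR")`
#'   for logistic dependence on age.
#' @param seed Integer seed (mandatory: all generation is reproducible).
#' @param spec An [msm_spec()].
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 1000,
                       rates = default_true_rates(),
                       betas = NULL,
                       visit_rate = 2,
                       horizon = NULL,
                       p_female = 0.562, p_type2 = 0.931, p_smoker = 0.428,
                       age_mean = 54.7, age_sd = 14.1,
                       covariate_dists = NULL,
                       missingness = list(hba1c = 0.15, ldl = 0.40,
                                          bmi = 0.05, sbp = 0.01, adi = 0.074),
                       seed = 1L,
                       spec = msm_spec()) {
  stopifnot(n_patients >= 1, visit_rate >= 0, all(rates >= 0))
  for (m in missingness) {
    p <- if (is.list(m)) m$p else m
    stopifnot(p >= 0, p <= 1)
  }
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  # any true-effect covariate not otherwise specified defaults to Bernoulli(0.5)
  if (!is.null(betas)) {
    base_vars <- c("female", "age", "type2", "smoker", "adi_decile")
    extra <- setdiff(unique(unlist(lapply(betas, names))),
                     c(base_vars, names(covariate_dists)))
    for (e in extra) covariate_dists[[e]] <- list(kind = "bernoulli", p = 0.5)
  }
  structure(list(n_patients = as.integer(n_patients), rates = rates,
                 betas = betas, visit_rate = visit_rate, horizon = horizon,
                 p_female = p_female, p_type2 = p_type2, p_smoker = p_smoker,
                 age_mean = age_mean, age_sd = age_sd,
                 covariate_dists = covariate_dists,
                 missingness = missingness, seed = as.integer(seed),
                 spec = spec), class = "sim_config")
}

#' Default true transition intensities of the synthetic generator
#'
#' The four forward complication intensities (DM to Micro 0.1334, DM to
#' Macro 0.0508, Micro to Both 0.0395, Macro to Both 0.0784 per
#' person-year) with death intensities calibrated so the one-year death
#' probabilities from each living state are 0.4%, 0.2%, 0.3% and 1.3%.
#'
#' @return Named numeric vector over the 8 allowed transitions.
#' @export
default_true_rates <- function() {
  calibrate_death_intensities(
    c("DM->Micro" = 0.1334, "DM->Macro" = 0.0508,
      "Micro->Both" = 0.0395, "Macro->Both" = 0.0784),
    death_probs = c(0.004, 0.002, 0.003, 0.013), t = 1)
}

## Draw the baseline covariate table of a synthetic cohort.
draw_covariates <- function(config) {
  n <- config$n_patients
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    female = stats::rbinom(n, 1, config$p_female),
    age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
    type2 = stats::rbinom(n, 1, config$p_type2),
    smoker = stats::rbinom(n, 1, config$p_smoker),
    adi_decile = sample.int(10, n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (nm in names(config$covariate_dists)) {
    d <- config$covariate_dists[[nm]]
    out[[nm]] <- switch(d$kind,
      bernoulli = stats::rbinom(n, 1, d$p),
      normal = stats::rnorm(n, d$mean, d$sd),
      categorical = sample(names(d$probs), n, replace = TRUE,
                           prob = unlist(d$probs)),
      stop("unknown covariate distribution kind: ", d$kind))
  }
  out
}

#' Simulate a panel-observed cohort directly (no EHR tables)
#'
#' Draws covariates, builds each patient's generator from the true
#' intensities and log hazard ratios, simulates the true trajectory,
#' samples ambulatory visit times from a homogeneous Poisson process
#' (plus a guaranteed index visit at time 0), and emits the observation
#' records the panel likelihood consumes: the current true state at each
#' visit, the exact death time, and a state-level-censored record at the
#' end of follow-up.
#'
#' @param config A [sim_config()].
#' @return List with `observations`, `covariates`, and `truth` (true
#'   parameters and per-patient trajectories).
#' @export
simulate_panel_cohort <- function(config) {
  set.seed(config$seed)
  spec <- config$spec
  cov <- draw_covariates(config)
  n <- config$n_patients
  horizons <- if (is.null(config$horizon)) stats::runif(n, 2, 7)
              else if (is.function(config$horizon)) config$horizon(n)
              else rep(config$horizon, n)
  if (config$visit_rate == 0 && any(config$rates > 0))
    message("visit_rate is 0 with nonzero intensities: transitions are ",
            "unobservable before death or censoring")

  states <- spec$states
  death_name <- if (!is.null(spec$death)) states[spec$death] else NULL
  # accumulate flat vectors; building one data frame at the end keeps the
  # generator fast enough for replicated simulation studies
  o_id <- list(); o_t <- list(); o_s <- list(); o_k <- list(); o_c <- list()
  tr_id <- list(); tr_t <- list(); tr_s <- list(); tr_e <- list(); tr_st <- list()
  cens_cache <- lapply(seq_along(states), function(r)
    paste(states[censor_set_for(spec, r)], collapse = "|"))

  for (i in seq_len(n)) {
    z <- c(female = cov$female[i], age = cov$age[i], type2 = cov$type2[i],
           smoker = cov$smoker[i], adi_decile = cov$adi_decile[i])
    for (e in names(config$covariate_dists)) z[e] <- as.numeric(cov[[e]][i])
    Q <- build_generator(config$rates, betas = config$betas, z = z, spec = spec)
    traj <- simulate_trajectory(Q, horizons[i])
    nv <- stats::rpois(1, config$visit_rate * horizons[i])
    visits <- sort(c(0, stats::runif(nv, 0, horizons[i])))

    died <- !is.null(death_name) && traj$status == "absorbed" &&
      traj$state[length(traj$state)] == death_name
    if (died) visits <- visits[visits < traj$end_time]
    vstates <- traj$state[pmax(findInterval(visits, traj$time), 1L)]
    tt <- visits; ss <- vstates
    kk <- rep("panel", length(visits)); cc <- rep(NA_character_, length(visits))
    if (died) {
      tt <- c(tt, traj$end_time); ss <- c(ss, death_name)
      kk <- c(kk, "exact_death"); cc <- c(cc, NA_character_)
    } else if (horizons[i] > max(visits)) {
      last <- ss[length(ss)]
      tt <- c(tt, horizons[i]); ss <- c(ss, last)
      kk <- c(kk, "censored"); cc <- c(cc, cens_cache[[match(last, states)]])
    }
    o_id[[i]] <- rep(cov$patient_id[i], length(tt))
    o_t[[i]] <- tt; o_s[[i]] <- ss; o_k[[i]] <- kk; o_c[[i]] <- cc
    tr_id[[i]] <- rep(cov$patient_id[i], length(traj$time))
    tr_t[[i]] <- traj$time; tr_s[[i]] <- traj$state
    tr_e[[i]] <- rep(traj$end_time, length(traj$time))
    tr_st[[i]] <- rep(traj$status, length(traj$time))
  }
  observations <- data.frame(
    patient_id = unlist(o_id), time = unlist(o_t), state = unlist(o_s),
    kind = unlist(o_k), censor_set = unlist(o_c), stringsAsFactors = FALSE)
  truth_traj <- data.frame(
    patient_id = unlist(tr_id), time = unlist(tr_t), state = unlist(tr_s),
    end_time = unlist(tr_e), status = unlist(tr_st), stringsAsFactors = FALSE)
  list(observations = observations,
       covariates = cov,
       truth = list(rates = config$rates, betas = config$betas,
                    seed = config$seed, trajectories = truth_traj))
}

## Binary covariate helper used in recovery / screening experiments:
## adds iid Bernoulli(0.5) columns to a generated covariate table.
add_binary_covariates <- function(cohort, names, p = 0.5) {
  n <- nrow(cohort$covariates)
  for (nm in names) cohort$covariates[[nm]] <- stats::rbinom(n, 1, p)
  cohort
}
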