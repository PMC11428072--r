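## Synthetic EHR-table emission: wraps the trajectory simulator in
## dated tables (patients, visits, diagnoses, labs, deaths, adi) shaped
## like a primary-care extract, so the cohort builder can be exercised
## end to end against known truth.

#' Generate a synthetic EHR cohort as linked tables
#'
#' Simulates true five-state trajectories per patient and renders them
#' as EHR-style tables: a guaranteed index ambulatory visit, Poisson
#' follow-up visits, a prior hospital visit (eight months before index,
#' establishing prior-patient history), a diabetes diagnosis code at
#' index, complication codes for the patient's cumulative true state at
#' every follow-up visit (so transition times are interval-censored
#' between visits), exact death dates, HbA1c labs, an ADI decile table,
#' and a baseline covariate table with configurable missingness (MCAR,
#' or MAR depending logistically on age).  A truth sidecar carries the
#' generating parameters and the true trajectories.
#'
#' @param config A [sim_config()]; `horizon` is ignored in favour of
#'   per-patient follow-up from a uniform index date in the study
#'   window through `followup_end`.
#' @param codesets Code dictionaries used to emit diagnosis codes.
#' @param study_start,study_end Index visits fall in this window.
#' @param followup_end End of follow-up.
#' @param dir Optional directory: tables are written as CSV plus a
#'   `truth.json` sidecar.
#' @return List with `tables` (list of data frames: patients, visits,
#'   diagnoses, labs, deaths, adi), `baseline` (covariate table with
#'   injected missingness), and `truth`.
#' @export
generate_cohort <- function(config, codesets = default_codesets(),
                            study_start = "2013-01-01",
                            study_end = "2017-12-31",
                            followup_end = "2019-12-31",
                            dir = NULL) {
  set.seed(config$seed)
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  followup_end <- as.Date(followup_end)
  spec <- config$spec
  n <- config$n_patients
  cov <- draw_covariates(config)
  index_date <- study_start +
    floor(stats::runif(n, 0, as.numeric(study_end - study_start) + 1))
  horizon <- as.numeric(followup_end - index_date) / 365.25
  if (config$visit_rate == 0 && any(config$rates > 0))
    message("visit_rate is 0 with nonzero intensities: transitions are ",
            "unobservable before death or censoring")

  sys_of <- function(code) ifelse(code %in% codesets$cpt, "CPT",
                           ifelse(grepl("^[A-Z]", code), "ICD10", "ICD9"))
  visits <- list(); diagnoses <- list(); labs <- list(); deaths <- list()
  truth_traj <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- cov$patient_id[i]; idx <- index_date[i]
    z <- c(female = cov$female[i], age = cov$age[i], type2 = cov$type2[i],
           smoker = cov$smoker[i], adi_decile = cov$adi_decile[i])
    for (e in names(config$covariate_dists)) z[e] <- as.numeric(cov[[e]][i])
    Q <- build_generator(config$rates, betas = config$betas, z = z, spec = spec)
    traj <- simulate_trajectory(Q, horizon[i])
    died <- traj$status == "absorbed" &&
      traj$state[length(traj$state)] == "Death"
    death_t <- if (died) traj$end_time else Inf

    nv <- stats::rpois(1, config$visit_rate * horizon[i])
    vt <- sort(c(0, stats::runif(nv, 0, horizon[i])))
    vt <- vt[vt < death_t]
    vdates <- unique(idx + round(vt * 365.25))
    visits[[i]] <- data.frame(
      patient_id = pid,
      date = c(idx - 240, vdates),
      setting = c("hospital", rep("ambulatory", length(vdates))))

    state_at <- function(tt) traj$state[max(findInterval(tt, traj$time), 1L)]
    vstates <- vapply((as.numeric(vdates - idx)) / 365.25, state_at, character(1))
    dg <- data.frame(patient_id = pid, date = idx,
                     code = codesets$dm[1 + (i %% length(codesets$dm))])
    for (j in seq_along(vdates)) {
      s <- vstates[j]
      if (s %in% c("Micro", "Both"))
        dg <- rbind(dg, data.frame(patient_id = pid, date = vdates[j],
                                   code = sample(codesets$micro, 1)))
      if (s %in% c("Macro", "Both"))
        dg <- rbind(dg, data.frame(patient_id = pid, date = vdates[j],
                                   code = sample(codesets$macro, 1)))
    }
    dg$system <- sys_of(dg$code)
    diagnoses[[i]] <- dg

    labs[[i]] <- data.frame(
      patient_id = pid, date = c(idx, vdates),
      analyte = "hba1c",
      value = round(stats::rnorm(length(vdates) + 1, 7.5, 1.5), 1),
      units = "%")
    if (died)
      deaths[[i]] <- data.frame(patient_id = pid,
                                date = idx + round(death_t * 365.25))
    truth_traj[[i]] <- data.frame(patient_id = pid, time = traj$time,
                                  state = traj$state, end_time = traj$end_time,
                                  status = traj$status)
  }

  patients <- data.frame(
    patient_id = cov$patient_id,
    birth_date = index_date - round(cov$age * 365.25),
    sex = ifelse(cov$female == 1, "F", "M"),
    race = sample(c("White", "Black", "Other"), n, replace = TRUE,
                  prob = c(0.643, 0.284, 0.073)),
    ethnicity = sample(c("Non-Hispanic", "Hispanic"), n, replace = TRUE,
                       prob = c(0.92, 0.08)),
    insurance = sample(c("Commercial", "Medicare", "Medicaid", "Self-pay"),
                       n, replace = TRUE, prob = c(0.658, 0.286, 0.019, 0.037)),
    dm_type = ifelse(cov$type2 == 1, "type2", "type1"),
    smoking = ifelse(cov$smoker == 1, "ever", "never"))
  adi <- data.frame(patient_id = cov$patient_id, decile = cov$adi_decile)

  baseline <- cov
  baseline$hba1c <- round(stats::rnorm(n, 7.5, 1.5), 1)
  baseline$ldl <- round(stats::rnorm(n, 100, 30), 0)
  baseline$bmi <- round(stats::rnorm(n, 31, 6), 1)
  baseline$sbp <- round(stats::rnorm(n, 131, 15), 0)
  baseline$adi_decile <- adi$decile
  baseline <- inject_missingness(baseline, config$missingness,
                                 map = c(adi = "adi_decile"))

  tables <- list(patients = patients,
                 visits = do.call(rbind, visits),
                 diagnoses = do.call(rbind, diagnoses),
                 labs = do.call(rbind, labs),
                 deaths = if (length(deaths)) do.call(rbind, deaths) else
                   data.frame(patient_id = character(0), date = as.Date(character(0))),
                 adi = adi)
  truth <- list(rates = as.list(config$rates), betas = config$betas,
                seed = config$seed,
                study_start = as.character(study_start),
                study_end = as.character(study_end),
                followup_end = as.character(followup_end),
                index_dates = stats::setNames(as.character(index_date),
                                              cov$patient_id),
                trajectories = do.call(rbind, truth_traj))
  out <- list(tables = tables, baseline = baseline, truth = truth)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

## Inject per-variable missingness: MCAR, or MAR with logistic
## dependence on age (older patients more likely to be missing).
inject_missingness <- function(df, missingness, map = character(0)) {
  n <- nrow(df)
  for (nm in names(missingness)) {
    m <- missingness[[nm]]
    p <- if (is.list(m)) m$p else m
    mech <- if (is.list(m) && !is.null(m$mechanism)) m$mechanism else "MCAR"
    col <- if (nm %in% names(map)) map[[nm]] else nm
    if (!col %in% names(df)) next
    if (mech == "MAR") {
      a <- scale(df$age)[, 1]
      eta <- stats::qlogis(p) + 0.8 * a
      miss <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
    } else {
      miss <- stats::runif(n) < p
    }
    df[[col]][miss] <- NA
  }
  df
}

#' Write a synthetic cohort to disk
#'
#' Writes the linked tables as CSV (ISO-8601 dates, header row, UTF-8)
#' plus `baseline.csv` and a JSON truth sidecar.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$tables))
    utils::write.csv(cohort$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir Directory holding the CSV tables.
#' @return List with `tables`, `baseline`, and `truth` (when the
#'   sidecar is present).
#' @export
read_cohort <- function(dir) {
  need <- c("patients", "visits", "diagnoses", "labs", "deaths", "adi")
  tables <- list()
  for (nm in need) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing input table: ", f)
    tables[[nm]] <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  bl <- file.path(dir, "baseline.csv")
  tj <- file.path(dir, "truth.json")
  list(tables = tables,
       baseline = if (file.exists(bl)) utils::read.csv(bl) else NULL,
       truth = if (file.exists(tj)) jsonlite::read_json(tj, simplifyVector = TRUE) else NULL)
}
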