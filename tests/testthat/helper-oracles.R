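# Independent oracles for the multistate engine.  These deliberately
# avoid the package's computation paths: transition probabilities come
# from phase-type path sums (partial-fraction form of convolved
# exponentials on the progressive DAG), and the panel likelihood from a
# direct R loop over Matrix::expm.

# P[r,s](t) as a sum over all directed paths r -> s in the allowed-
# transition DAG.  For a path (i_0..i_m) with total exit rates lam,
# the probability of having made exactly those jumps and sitting in i_m
# at time t is prod(q) * sum_l exp(-lam_l t) / prod_{j != l}(lam_j - lam_l).
# Requires distinct exit rates along each path (a.s. for random rates).
oracle_pmatrix <- function(Q, t) {
  n <- nrow(Q)
  lam <- -diag(Q)
  contrib <- function(path) {
    q <- 1
    m <- length(path)
    if (m > 1) for (l in seq_len(m - 1)) q <- q * Q[path[l], path[l + 1]]
    lp <- lam[path]
    s <- 0
    for (l in seq_len(m)) s <- s + exp(-lp[l] * t) / prod(lp[-l] - lp[l])
    q * s
  }
  P <- matrix(0, n, n, dimnames = dimnames(Q))
  for (r in seq_len(n)) {
    walk <- function(path) {
      last <- path[length(path)]
      P[r, last] <<- P[r, last] + contrib(path)
      for (k in seq_len(n))
        if (k != last && Q[last, k] > 0) walk(c(path, k))
    }
    walk(r)
  }
  P
}

# Panel log-likelihood by brute force: Matrix::expm per interval.
oracle_loglik <- function(params, observations, spec, Q = NULL) {
  ntrans <- nrow(spec$transitions)
  if (is.null(Q))
    Q <- build_generator(stats::setNames(exp(params[seq_len(ntrans)]),
                                         spec$labels), spec = spec)
  ob <- observations[order(observations$patient_id, observations$time), ]
  ll <- 0
  for (pid in unique(ob$patient_id)) {
    o <- ob[ob$patient_id == pid, ]
    for (j in seq_len(nrow(o) - 1)) {
      dt <- o$time[j + 1] - o$time[j]
      P <- as.matrix(Matrix::expm(Q * dt))
      r <- match(o$state[j], spec$states)
      if (o$kind[j + 1] == "panel") {
        ll <- ll + log(P[r, match(o$state[j + 1], spec$states)])
      } else if (o$kind[j + 1] == "exact_death") {
        d <- spec$death
        ll <- ll + log(sum(P[r, -d] * Q[-d, d]))
      } else {
        cs <- match(strsplit(o$censor_set[j + 1], "|", fixed = TRUE)[[1]],
                    spec$states)
        ll <- ll + log(sum(P[r, cs]))
      }
    }
  }
  ll
}

# Random valid generator on the 5-state progressive mask.
random_generator <- function(lo = 0.02, hi = 0.8) {
  sp <- msm_spec()
  build_generator(stats::setNames(stats::runif(8, lo, hi), sp$labels), spec = sp)
}

# The four printed forward intensities and one-year death-column
# targets used throughout the consistency suite.
printed_forward_rates <- function() {
  c("DM->Micro" = 0.1334, "DM->Macro" = 0.0508,
    "Micro->Both" = 0.0395, "Macro->Both" = 0.0784)
}
printed_death_probs <- function() c(0.004, 0.002, 0.003, 0.013)

# Hand-built 10-patient EHR fixture exercising each exclusion rule once.
# Intended survivors: P01 (clean), P02 (clean), P10 (clean); P09 is the
# same-date micro+macro tie (excluded under "none", kept under
# reassignment).  Hand tally of the cascade, applied in order:
#   P03 no DM code                      -> rule 1
#   P04 aged 17 at index                -> rule 2
#   P05 macro code in 2011              -> rule 3
#   P06 no ambulatory follow-up         -> rule 4
#   P07 no HbA1c ever                   -> rule 5
#   P08 first DM at index, no history   -> rule 6
#   P09 micro+macro both on 2014-06-01  -> rule 7
#   P11 no ambulatory visit in window   -> not in index map
cohort_fixture <- function() {
  d <- function(x) as.Date(x)
  visits <- rbind(
    data.frame(patient_id = "P01", date = d(c("2010-05-01", "2013-02-01", "2014-02-01", "2016-02-01")),
               setting = c("hospital", "ambulatory", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P02", date = d(c("2012-01-01", "2013-03-01", "2015-03-01")),
               setting = c("ambulatory", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P03", date = d(c("2010-01-01", "2013-04-01", "2014-04-01")),
               setting = c("hospital", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P04", date = d(c("2010-01-01", "2013-05-01", "2014-05-01")),
               setting = c("hospital", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P05", date = d(c("2010-01-01", "2013-06-01", "2014-06-01")),
               setting = c("hospital", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P06", date = d(c("2010-01-01", "2013-07-01")),
               setting = c("hospital", "ambulatory")),
    data.frame(patient_id = "P07", date = d(c("2010-01-01", "2013-08-01", "2014-08-01")),
               setting = c("hospital", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P08", date = d(c("2013-09-01", "2014-09-01")),
               setting = c("ambulatory", "ambulatory")),
    data.frame(patient_id = "P09", date = d(c("2010-01-01", "2013-10-01", "2014-06-01", "2015-06-01")),
               setting = c("hospital", "ambulatory", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P10", date = d(c("2010-01-01", "2013-11-01", "2014-11-01", "2016-11-01")),
               setting = c("hospital", "ambulatory", "ambulatory", "ambulatory")),
    data.frame(patient_id = "P11", date = d(c("2010-01-01", "2011-02-01")),
               setting = c("hospital", "ambulatory")))
  # everyone gets a DM code on their first in-window ambulatory visit,
  # except P03 (no DM code) and P08 (DM first coded at index, no prior
  # history).  P01 also has an older DM code so rule 6 passes.
  diagnoses <- rbind(
    data.frame(patient_id = "P01", date = d(c("2010-05-01", "2013-02-01", "2014-02-01")),
               code = c("250.00", "E11.9", "E11.21"), system = c("ICD9", "ICD10", "ICD10")),
    data.frame(patient_id = "P02", date = d(c("2012-01-01", "2013-03-01")),
               code = c("E11.9", "E11.9"), system = "ICD10"),
    data.frame(patient_id = "P03", date = d("2013-04-01"),
               code = "I10", system = "ICD10"),        # hypertension, not DM
    data.frame(patient_id = "P04", date = d(c("2010-01-01", "2013-05-01")),
               code = c("E11.9", "E11.9"), system = "ICD10"),
    data.frame(patient_id = "P05", date = d(c("2010-01-01", "2011-06-15", "2013-06-01")),
               code = c("E11.9", "I25.10", "E11.9"), system = "ICD10"),
    data.frame(patient_id = "P06", date = d(c("2010-01-01", "2013-07-01")),
               code = c("E11.9", "E11.9"), system = "ICD10"),
    data.frame(patient_id = "P07", date = d(c("2010-01-01", "2013-08-01")),
               code = c("E11.9", "E11.9"), system = "ICD10"),
    data.frame(patient_id = "P08", date = d("2013-09-01"),
               code = "E11.9", system = "ICD10"),
    data.frame(patient_id = "P09", date = d(c("2010-01-01", "2014-06-01", "2014-06-01")),
               code = c("E11.9", "E11.21", "I25.10"), system = "ICD10"),
    data.frame(patient_id = "P10", date = d(c("2010-01-01", "2014-11-01", "2016-11-01")),
               code = c("E11.9", "E11.21", "I25.10"), system = "ICD10"),
    data.frame(patient_id = "P11", date = d("2011-02-01"),
               code = "E11.9", system = "ICD10"))
  labs <- data.frame(
    patient_id = c("P01", "P02", "P04", "P05", "P06", "P08", "P09", "P10"),
    date = d(c("2013-02-01", "2013-03-01", "2013-05-01", "2013-06-01",
               "2013-07-01", "2013-09-01", "2013-10-01", "2013-11-01")),
    analyte = "hba1c", value = 7.5, units = "%")
  birth <- function(age_at, idx) d(idx) - round(age_at * 365.25)
  patients <- data.frame(
    patient_id = sprintf("P%02d", 1:11),
    birth_date = c(birth(60, "2013-02-01"), birth(50, "2013-03-01"),
                   birth(55, "2013-04-01"), birth(17, "2013-05-01"),
                   birth(45, "2013-06-01"), birth(70, "2013-07-01"),
                   birth(52, "2013-08-01"), birth(48, "2013-09-01"),
                   birth(63, "2013-10-01"), birth(58, "2013-11-01"),
                   birth(40, "2013-01-01")),
    sex = "F", race = "White", ethnicity = "Non-Hispanic",
    insurance = "Commercial", dm_type = "type2", smoking = "never")
  deaths <- data.frame(patient_id = "P02", date = d("2015-09-01"))
  adi <- data.frame(patient_id = patients$patient_id, decile = 1:11 %% 10 + 1)
  list(patients = patients, visits = visits, diagnoses = diagnoses,
       labs = labs, deaths = deaths, adi = adi)
}
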