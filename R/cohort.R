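#' Illustrative complication code sets
#'
#' Small built-in ICD9/ICD10/CPT code lists for diabetes, microvascular
#' complications (nephropathy, neuropathy, retinopathy), macrovascular
#' complications (cardiovascular, peripheral vascular, foot non-ulcer),
#' diabetes-related complication codes, and complication-related CPT
#' procedure codes.  These are illustrative defaults: real analyses
#' should supply their own dictionaries via [read_codesets()].
#'
#' @return List of class `"codesets"` with character-vector elements
#'   `dm`, `micro`, `macro`, `dm_related`, `cpt`.
#' @export
default_codesets <- function() {
  new_codesets(list(
    dm = c("250.00", "250.01", "E10.9", "E11.9", "E13.9"),
    micro = c("250.40", "250.60", "357.2", "362.01", "583.81",
              "E10.40", "E11.21", "E11.22", "E11.311", "E11.42"),
    macro = c("410.90", "414.01", "433.10", "440.9", "443.9",
              "I21.9", "I25.10", "I63.9", "I70.209", "E11.51"),
    dm_related = c("585.9", "N18.9", "H35.00", "354.0"),
    cpt = c("92250", "93922", "66821")))
}

new_codesets <- function(x) {
  need <- c("dm", "micro", "macro", "dm_related", "cpt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("codesets lack section(s): ", paste(miss, collapse = ", "))
  x <- lapply(x[need], as.character)
  both <- intersect(x$micro, x$macro)
  if (length(both))
    stop("code(s) in both micro and macro sets: ", paste(both, collapse = ", "))
  structure(x, class = "codesets")
}

#' Read complication code sets from a YAML file
#'
#' The file must have sections `dm`, `micro`, `macro`, `dm_related`,
#' `cpt`, each a list of code strings.  A code present in both the
#' micro and macro sets is a configuration error.
#'
#' @param path Path to the YAML file.
#' @return A `"codesets"` list as from [default_codesets()].
#' @export
read_codesets <- function(path) new_codesets(yaml::read_yaml(path))

#' Classify a diagnosis code as micro- or macrovascular
#'
#' @param code Character vector of code strings.
#' @param codesets A `"codesets"` list.
#' @return Character vector: `"Micro"`, `"Macro"`, or `NA` for codes in
#'   neither set.
#' @export
classify_code <- function(code, codesets = default_codesets()) {
  out <- rep(NA_character_, length(code))
  out[code %in% codesets$micro] <- "Micro"
  out[code %in% codesets$macro] <- "Macro"
  out
}

#' Biological ascertainment of chronic kidney disease
#'
#' CKD is ascertained from two estimated glomerular filtration rates
#' below 60 mL/min/1.73m^2 at least 90 days apart, or two abnormal
#' albuminuria/proteinuria results at least 90 days apart.  Returns the
#' date of the second qualifying measurement of the first satisfied
#' pair; when both criteria are met, the earlier date wins.  A CKD
#' event counts as a microvascular (nephropathy) outcome.
#'
#' @param labs Data frame of one patient's labs with columns `date`,
#'   `analyte` (`"egfr"`, `"albuminuria"`, `"proteinuria"`, ...),
#'   `value`, and optionally `abnormal` (logical, for
#'   albuminuria/proteinuria rows).
#' @return The CKD ascertainment `Date`, or `NA` if the rule is not met.
#' @export
ascertain_ckd <- function(labs) {
  if (!nrow(labs)) return(as.Date(NA))
  labs$date <- as.Date(labs$date)
  qualifying_second <- function(dates) {
    if (length(dates) < 2L) return(as.Date(NA))
    dates <- sort(dates)
    ok <- vapply(seq_along(dates),
                 function(j) any(dates[seq_len(j - 1)] <= dates[j] - 90),
                 logical(1))
    if (any(ok)) dates[which(ok)[1]] else as.Date(NA)
  }
  egfr <- labs$date[labs$analyte == "egfr" & !is.na(labs$value) & labs$value < 60]
  alb <- labs$date[labs$analyte %in% c("albuminuria", "proteinuria") &
                     isTRUE_vec(labs$abnormal)]
  cand <- c(qualifying_second(egfr), qualifying_second(alb))
  if (all(is.na(cand))) as.Date(NA) else min(cand, na.rm = TRUE)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Find each patient's index visit
#'
#' The index visit is the date of a patient's first ambulatory visit
#' inside the study window; patients with no ambulatory visit in the
#' window are dropped.
#'
#' @param visits Data frame with `patient_id`, `date`, `setting`
#'   (`"ambulatory"` or `"hospital"`).
#' @param study_start,study_end Study window (dates, inclusive).
#' @return Named `Date` vector, one index date per included patient.
#' @export
find_index_visit <- function(visits, study_start, study_end) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_end < study_start) stop("empty study window")
  v <- visits[visits$setting == "ambulatory", , drop = FALSE]
  v$date <- as.Date(v$date)
  v <- v[v$date >= study_start & v$date <= study_end, , drop = FALSE]
  if (!nrow(v)) return(stats::setNames(as.Date(character(0)), character(0)))
  agg <- stats::aggregate(date ~ patient_id, data = v, FUN = min)
  stats::setNames(agg$date, agg$patient_id)
}

## First micro / first macro event dates (codes at or after the index
## date, plus biological CKD as a micro event).
first_complication_dates <- function(tables, codesets, pid, index_date) {
  dg <- tables$diagnoses[tables$diagnoses$patient_id == pid, , drop = FALSE]
  dg$date <- as.Date(dg$date)
  dg <- dg[dg$date >= index_date, , drop = FALSE]
  cls <- classify_code(dg$code, codesets)
  fm <- suppressWarnings(min(dg$date[!is.na(cls) & cls == "Micro"]))
  fM <- suppressWarnings(min(dg$date[!is.na(cls) & cls == "Macro"]))
  ckd <- ascertain_ckd(tables$labs[tables$labs$patient_id == pid, , drop = FALSE])
  if (!is.na(ckd) && ckd >= index_date) fm <- min(fm, ckd)
  list(micro = fm, macro = fM)
}

#' Apply the cohort inclusion/exclusion cascade
#'
#' Applies, in order: (1) has a diabetes diagnosis code; (2) age 18 or
#' older at index; (3) no complication, complication-related, or
#' complication CPT code before the study period; (4) at least one
#' ambulatory follow-up visit after index; (5) at least one HbA1c at
#' index or during follow-up; (6) not a first diabetes diagnosis at
#' index without prior history (a prior visit in either setting at
#' least six months before index); (7) first micro- and macrovascular
#' complications not coded on the same date (order undeterminable).
#' Emits a flowchart-style audit table of per-rule exclusion counts.
#'
#' @param tables List of cohort tables: `patients`, `visits`,
#'   `diagnoses`, `labs`, `deaths`, `adi` (see [generate_cohort()]).
#' @param codesets A `"codesets"` list.
#' @param index_map Named date vector from [find_index_visit()].
#' @param study_start Start of the study period (codes before it count
#'   as prior history of complications).
#' @return List with `included` (patient ids), `ties` (ids excluded by
#'   rule 7, needed for reassignment sensitivity analyses), and `audit`
#'   (data frame of rule labels and counts).
#' @export
apply_exclusions <- function(tables, codesets, index_map, study_start) {
  study_start <- as.Date(study_start)
  dg <- tables$diagnoses
  ok_sys <- dg$system %in% c("ICD9", "ICD10", "CPT")
  if (!all(ok_sys)) {
    bad <- which(!ok_sys)[1]
    stop("unknown code system '", dg$system[bad], "' in diagnoses row ", bad,
         " (patient ", dg$patient_id[bad], ")")
  }
  dg$date <- as.Date(dg$date)
  ids <- names(index_map)
  audit <- data.frame(rule = character(0), excluded = integer(0))
  note <- function(rule, drop) {
    audit <<- rbind(audit, data.frame(rule = rule, excluded = sum(drop)))
    ids[!drop]
  }

  # 1: diabetes diagnosis required
  has_dm <- ids %in% dg$patient_id[dg$code %in% codesets$dm]
  ids <- note("no DM diagnosis code", !has_dm)

  # 2: adults only
  pt <- tables$patients[match(ids, tables$patients$patient_id), , drop = FALSE]
  age <- floor(as.numeric(index_map[ids] - as.Date(pt$birth_date)) / 365.25)
  ids <- note("age < 18 at index visit", age < 18)

  # 3: complications before the study period
  compl_codes <- c(codesets$micro, codesets$macro, codesets$dm_related, codesets$cpt)
  prior <- ids %in% dg$patient_id[dg$code %in% compl_codes & dg$date < study_start]
  ids <- note("complication coded before study period", prior)

  # 4: ambulatory follow-up after index
  v <- tables$visits; v$date <- as.Date(v$date)
  amb <- v[v$setting == "ambulatory", , drop = FALSE]
  has_fu <- vapply(ids, function(p)
    any(amb$patient_id == p & amb$date > index_map[p]), logical(1))
  ids <- note("no ambulatory follow-up visit", !has_fu)

  # 5: HbA1c at index or follow-up
  lb <- tables$labs; lb$date <- as.Date(lb$date)
  a1c <- lb[lb$analyte == "hba1c", , drop = FALSE]
  has_a1c <- vapply(ids, function(p)
    any(a1c$patient_id == p & a1c$date >= index_map[p]), logical(1))
  ids <- note("no HbA1c at index or follow-up", !has_a1c)

  # 6: first DM diagnosis at index without prior-patient history
  first_dm <- vapply(ids, function(p)
    as.numeric(suppressWarnings(min(dg$date[dg$patient_id == p &
                                              dg$code %in% codesets$dm]))),
    numeric(1))
  new_at_index <- first_dm == as.numeric(index_map[ids])
  has_history <- vapply(ids, function(p)
    any(v$patient_id == p & v$date <= index_map[p] - 183), logical(1))
  ids <- note("first DM at index, not a prior patient", new_at_index & !has_history)

  # 7: first micro and macro complication on the same date
  tie <- vapply(ids, function(p) {
    fc <- first_complication_dates(tables, codesets, p, index_map[p])
    is.finite(fc$micro) && is.finite(fc$macro) && fc$micro == fc$macro
  }, logical(1))
  tie_ids <- ids[tie]
  ids <- note("simultaneous first micro + macro complication", tie)

  list(included = ids, ties = tie_ids, audit = audit)
}

#' Build panel observation records for the multistate model
#'
#' For each patient, emits one panel record per ambulatory visit from
#' index onward carrying the cumulative complication state (`DM` until
#' the first complication; `Micro` or `Macro` after one type; `Both`
#' after one of each), an `exact_death` record at the death date when
#' the patient died by the end of follow-up, and otherwise a state-level
#' `censored` record at the end of follow-up when it lies beyond the
#' last visit.  Times are years since index, `(date - index)/365.25`.
#'
#' Patients whose first micro- and macrovascular complications share a
#' date are handled per `reassignment`: `"all_micro"` (`"all_macro"`)
#' records the assigned type at the tie visit and `Both` from the next
#' visit on; under `"none"` such patients must already be excluded.
#'
#' @inheritParams apply_exclusions
#' @param ids Patient ids to process (the cascade survivors, plus ties
#'   under a reassignment mode).
#' @param followup_end Last date of follow-up (deaths and visits beyond
#'   it are ignored).
#' @param reassignment `"none"`, `"all_micro"`, or `"all_macro"`.
#' @return Data frame of observation records (`patient_id`, `time`,
#'   `state`, `kind`, `censor_set`) ready for [msm_fit()].
#' @export
build_observations <- function(tables, codesets, index_map, ids, followup_end,
                               reassignment = c("none", "all_micro", "all_macro")) {
  reassignment <- match.arg(reassignment)
  followup_end <- as.Date(followup_end)
  spec <- msm_spec()
  v <- tables$visits; v$date <- as.Date(v$date)
  deaths <- tables$deaths; deaths$date <- as.Date(deaths$date)

  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    p <- ids[k]; idx <- index_map[[p]]
    dd <- deaths$date[deaths$patient_id == p]
    dd <- if (length(dd)) min(dd) else as.Date(NA)
    vis <- sort(unique(v$date[v$patient_id == p & v$setting == "ambulatory" &
                                v$date >= idx & v$date <= followup_end]))
    if (!is.na(dd) && any(vis > dd))
      stop("patient ", p, " has visits after the death date")
    fc <- first_complication_dates(tables, codesets, p, idx)
    tie <- is.finite(fc$micro) && is.finite(fc$macro) && fc$micro == fc$macro
    if (tie && reassignment == "none")
      stop("patient ", p, " has a same-date first micro+macro pair; ",
           "exclude it or use a reassignment mode")
    state_at <- function(d) {
      hm <- is.finite(fc$micro) && fc$micro <= d
      hM <- is.finite(fc$macro) && fc$macro <= d
      if (tie && d == fc$micro) {           # tie visit: assigned type first
        if (reassignment == "all_micro") hM <- FALSE else hm <- FALSE
      }
      if (hm && hM) "Both" else if (hm) "Micro" else if (hM) "Macro" else "DM"
    }
    yrs <- function(d) as.numeric(d - idx) / 365.25
    rec <- data.frame(patient_id = p, time = yrs(vis),
                      state = vapply(vis, state_at, character(1)),
                      kind = "panel", censor_set = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.na(dd) && dd <= followup_end) {
      rec <- rbind(rec, data.frame(patient_id = p, time = yrs(dd),
                                   state = "Death", kind = "exact_death",
                                   censor_set = NA_character_))
    } else if (followup_end > max(vis)) {
      last_state <- rec$state[nrow(rec)]
      cs <- censor_set_for(spec, match(last_state, spec$states))
      rec <- rbind(rec, data.frame(patient_id = p, time = yrs(followup_end),
                                   state = last_state, kind = "censored",
                                   censor_set = paste(spec$states[cs], collapse = "|")))
    }
    out[[k]] <- rec
  }
  do.call(rbind, out)
}
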