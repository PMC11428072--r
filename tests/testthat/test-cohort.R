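test_that("index visit selection picks the first in-window ambulatory visit", {
  v <- data.frame(
    patient_id = c("A", "A", "B", "B", "C"),
    date = as.Date(c("2012-06-01", "2013-03-01", "2014-01-05", "2014-01-05",
                     "2012-12-31")),
    setting = c("ambulatory", "ambulatory", "hospital", "ambulatory",
                "ambulatory"))
  idx <- find_index_visit(v, "2013-01-01", "2017-12-31")
  expect_equal(unname(idx["A"]), as.Date("2013-03-01"))  # pre-window visit ignored
  expect_equal(unname(idx["B"]), as.Date("2014-01-05"))  # ambulatory wins same day
  expect_false("C" %in% names(idx))                      # nothing in window
  expect_error(find_index_visit(v, "2017-01-01", "2013-01-01"), "empty")
})

test_that("CKD biological rule: two qualifying results >= 90 days apart", {
  d0 <- as.Date("2015-01-01")
  mk <- function(days, values) data.frame(patient_id = "X", date = d0 + days,
                                          analyte = "egfr", value = values)
  expect_equal(ascertain_ckd(mk(c(0, 100), c(55, 50))), d0 + 100)
  expect_true(is.na(ascertain_ckd(mk(0, 40))))                  # needs two
  expect_true(is.na(ascertain_ckd(mk(c(0, 89), c(55, 50)))))    # interval < 90
  expect_equal(ascertain_ckd(mk(c(0, 89, 95), c(55, 50, 58))), d0 + 95)
  # values >= 60 never qualify
  expect_true(is.na(ascertain_ckd(mk(c(0, 200), c(65, 61)))))
  # abnormal albuminuria pathway, earliest criterion wins
  lab <- rbind(mk(c(0, 120), c(55, 50)),
               data.frame(patient_id = "X", date = d0 + c(1, 95),
                          analyte = "albuminuria", value = 1))
  lab$abnormal <- c(NA, NA, TRUE, TRUE)
  expect_equal(ascertain_ckd(lab), d0 + 95)
})

test_that("code classification is a set lookup with disjointness enforced", {
  cs <- default_codesets()
  expect_identical(classify_code(cs$micro[1], cs), "Micro")
  expect_identical(classify_code(cs$macro[1], cs), "Macro")
  expect_true(is.na(classify_code("Z99.9", cs)))
  expect_error(dmpath:::new_codesets(list(dm = "a", micro = "x", macro = "x",
                                          dm_related = "b", cpt = "c")),
               "both micro and macro")
})

test_that("exclusion cascade on the hand fixture gives the hand-tallied audit", {
  tb <- cohort_fixture()
  cs <- default_codesets()
  idx <- find_index_visit(tb$visits, "2013-01-01", "2017-12-31")
  expect_equal(length(idx), 10L)  # P11 has no in-window ambulatory visit
  ex <- apply_exclusions(tb, cs, idx, "2013-01-01")
  expect_equal(ex$audit$excluded, rep(1L, 7))
  expect_setequal(ex$included, c("P01", "P02", "P10"))
  expect_identical(ex$ties, "P09")
  # audit counts plus survivors account for every patient entering
  expect_equal(sum(ex$audit$excluded) + length(ex$included), length(idx))
  # unknown code system is a hard error naming the row
  tb_bad <- tb
  tb_bad$diagnoses$system[3] <- "SNOMED"
  expect_error(apply_exclusions(tb_bad, cs, idx, "2013-01-01"), "SNOMED")
})

test_that("observation records carry cumulative states, death and censoring", {
  tb <- cohort_fixture()
  cs <- default_codesets()
  idx <- find_index_visit(tb$visits, "2013-01-01", "2017-12-31")
  ex <- apply_exclusions(tb, cs, idx, "2013-01-01")
  obs <- build_observations(tb, cs, idx, ex$included, "2019-12-31", "none")

  # P01: DM at index, Micro from the coded visit on, censored at study end
  o1 <- obs[obs$patient_id == "P01", ]
  expect_equal(o1$state, c("DM", "Micro", "Micro", "Micro"))
  expect_equal(o1$kind, c("panel", "panel", "panel", "censored"))
  expect_equal(o1$time[1], 0)
  expect_equal(o1$time[4], as.numeric(as.Date("2019-12-31") -
                                        as.Date("2013-02-01")) / 365.25)
  expect_identical(o1$censor_set[4], "Micro|Both")

  # P02 dies: exact death record at the death date, no trailing censor
  o2 <- obs[obs$patient_id == "P02", ]
  expect_identical(o2$kind[nrow(o2)], "exact_death")
  expect_equal(o2$time[nrow(o2)],
               as.numeric(as.Date("2015-09-01") - as.Date("2013-03-01")) / 365.25)

  # P10: micro then macro on a later visit -> Both from that visit onward
  o10 <- obs[obs$patient_id == "P10", ]
  expect_equal(o10$state[o10$kind == "panel"], c("DM", "Micro", "Both"))

  # tie patient under reassignment: assigned type at the tie visit,
  # Both from the following visit
  om <- build_observations(tb, cs, idx, "P09", "2019-12-31", "all_micro")
  expect_equal(om$state[om$kind == "panel"], c("DM", "Micro", "Both"))
  oM <- build_observations(tb, cs, idx, "P09", "2019-12-31", "all_macro")
  expect_equal(oM$state[oM$kind == "panel"], c("DM", "Macro", "Both"))
  expect_error(build_observations(tb, cs, idx, "P09", "2019-12-31", "none"),
               "reassignment")

  # a visit after the death date is a hard error
  tb_bad <- tb
  tb_bad$deaths$date <- as.Date("2014-01-01")
  expect_error(build_observations(tb_bad, cs, idx, "P02", "2019-12-31", "none"),
               "death")
})

test_that("hand-built sequence example: micro code, then death", {
  idx0 <- as.Date("2015-01-01")
  tb <- list(
    patients = data.frame(patient_id = "Z", birth_date = idx0 - 50 * 365.25,
                          sex = "F"),
    visits = data.frame(patient_id = "Z",
                        date = idx0 + round(c(0, 1, 2) * 365.25),
                        setting = "ambulatory"),
    diagnoses = data.frame(patient_id = "Z",
                           date = c(idx0, idx0 + round(365.25)),
                           code = c("E11.9", "E11.21"), system = "ICD10"),
    labs = data.frame(patient_id = "Z", date = idx0, analyte = "hba1c",
                      value = 8, units = "%"),
    deaths = data.frame(patient_id = "Z", date = idx0 + round(2.5 * 365.25)),
    adi = data.frame(patient_id = "Z", decile = 4))
  obs <- build_observations(tb, default_codesets(),
                            c(Z = idx0), "Z", "2019-12-31", "none")
  expect_equal(obs$state, c("DM", "Micro", "Micro", "Death"))
  expect_equal(obs$kind, c("panel", "panel", "panel", "exact_death"))
  expect_equal(obs$time, c(0, 1, 2, 2.5), tolerance = 0.01)
})

test_that("builder output on synthetic EHR matches the truth sidecar", {
  cfg <- sim_config(n_patients = 120, seed = 416)
  co <- generate_cohort(cfg)
  idx <- find_index_visit(co$tables$visits, "2013-01-01", "2017-12-31")
  ex <- apply_exclusions(co$tables, default_codesets(), idx, "2013-01-01")
  obs <- build_observations(co$tables, default_codesets(), idx, ex$included,
                            "2019-12-31", "none")
  tr <- co$truth$trajectories
  mismatch <- 0L
  for (p in unique(obs$patient_id)) {
    o <- obs[obs$patient_id == p & obs$kind == "panel", ]
    tp <- tr[tr$patient_id == p, ]
    true_state <- tp$state[pmax(findInterval(o$time + 1e-9, tp$time), 1L)]
    mismatch <- mismatch + sum(true_state != o$state)
  }
  expect_equal(mismatch, 0L)
})

test_that("codeset YAML round trip", {
  f <- tempfile(fileext = ".yaml")
  cs <- default_codesets()
  yaml::write_yaml(unclass(cs), f)
  expect_equal(read_codesets(f), cs)
})
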