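cfg <- study_config(seed = 5L)

test_that("follow-up windows apply the late-entry/early-exit rules", {
  # resident for the whole study
  w <- followup_window(civil_row("A", birth_date = "1990-04-01"), cfg)
  expect_equal(w$start, as.Date("2004-01-01"))
  expect_equal(w$end, as.Date("2017-04-23"))
  # 95th birthday before study start -> no window
  expect_null(followup_window(civil_row("B", birth_date = "1908-01-01"), cfg))
  # immigration starts, death ends
  w <- followup_window(civil_row(
    "C", birth_date = "1960-01-01", immigration_date = "2010-05-01",
    death_date = "2015-03-02"), cfg)
  expect_equal(w$start, as.Date("2010-05-01"))
  expect_equal(w$end, as.Date("2015-03-02"))
  # birth after start, emigration before end
  w <- followup_window(civil_row(
    "D", birth_date = "2006-08-09", emigration_date = "2012-01-15"), cfg)
  expect_equal(w$start, as.Date("2006-08-09"))
  expect_equal(w$end, as.Date("2012-01-15"))
  # censoring at the 95th birthday inside the window
  w <- followup_window(civil_row("E", birth_date = "1915-06-01"), cfg)
  expect_equal(w$end, as.Date("2010-06-01"))
})

test_that("case identification takes the earliest qualifying event in window", {
  catal <- default_disorder_catalogue()
  def <- catal[catal$disorder_name == "major depressive disorder", ]
  persons <- rbind(civil_row("P1", birth_date = "1980-01-01"),
                   civil_row("P2", birth_date = "1980-01-01"),
                   civil_row("P3", birth_date = "1996-01-01"))
  dx <- data.table::data.table(
    person_id = c("P1", "P1", "P2", "P3"),
    event_date = as.Date(c("2005-03-01", "2001-07-20", "1993-01-01",
                           "1998-06-01")),
    icd10_code = c("F32.1", "F33.0", "F32.9", "F32.0"),
    contact_type = "outpatient")
  cases <- identify_cases(dx, persons, def, cfg)
  # P1: earliest in-window event wins; P2: only pre-1995 -> not a case;
  # P3: aged 2 at the event, below the assumed earliest onset age (5) -> out
  expect_identical(cases$person_id, "P1")
  expect_equal(cases$index_date, as.Date("2001-07-20"))
  expect_error(
    regcost:::get_definition(catal, "no such disorder"),
    class = "regcost_unknown_disorder")
})

test_that("matching enforces every eligibility rule", {
  catal <- default_disorder_catalogue()
  def <- catal[catal$disorder_name == "schizophrenia", ]
  idx <- as.Date("2010-06-01")
  persons <- rbind(
    civil_row("CASE", "female", "1980-03-15"),
    civil_row("E1", "female", "1980-02-01"),                      # eligible
    civil_row("E2", "female", "1980-05-10"),                      # eligible
    civil_row("E3", "female", "1980-03-15"),                      # eligible
    civil_row("E4", "female", "1980-01-15"),                      # boundary, eligible
    civil_row("W1", "male", "1980-03-15"),                        # wrong sex
    civil_row("W2", "female", "1979-12-31"),                      # birth too early
    civil_row("W3", "female", "1980-05-16"),                      # birth too late
    civil_row("W4", "female", "1980-03-01", death_date = "2010-06-01"),  # dead at index
    civil_row("W5", "female", "1980-03-01", emigration_date = "2009-01-01"),
    civil_row("W6", "female", "1980-03-01", immigration_date = "2010-07-01"),
    civil_row("W7", "female", "1980-03-01")                       # dx before index
  )
  dx <- data.table::data.table(
    person_id = c("CASE", "W7"),
    event_date = c(idx, idx - 1L),
    icd10_code = "F20.0", contact_type = "inpatient")
  cases <- identify_cases(dx, persons, def, cfg)
  expect_identical(cases$person_id, c("W7", "CASE"))

  one_case <- cases[cases$person_id == "CASE", ]
  expect_warning(match_controls(one_case, persons, dx, def, cfg),
                 "fewer than 10 controls")
  ms <- suppressWarnings(match_controls(one_case, persons, dx, def, cfg))
  got <- sort(ms$controls$control_id)
  expect_identical(got, c("E1", "E2", "E3", "E4"))
  expect_identical(ms$sets$n_controls, 4L)
  # brute-force eligibility agrees
  expect_identical(got, oracle_eligible("CASE", idx, persons, dx, def, cfg))
  # the set passes its own invariant checker
  chk <- check_matched_sets(ms, persons, dx, catal, cfg)
  expect_true(all(chk$all_ok))
})

test_that("control sampling is seeded, capped at 10 and order-independent", {
  sim <- null_sim20()   # large pool so sampling is actually exercised
  catal <- default_disorder_catalogue()
  def <- catal[catal$disorder_name == "major depressive disorder", ]
  cases <- identify_cases(sim$bundle$psychiatric, sim$bundle$civil, def,
                          cfg)[1:60]
  ms1 <- suppressWarnings(match_controls(
    cases, sim$bundle$civil, sim$bundle$psychiatric, def, cfg))
  # permute inputs: identical sets
  perm_cases <- cases[rev(seq_len(nrow(cases))), ]
  perm_persons <- sim$bundle$civil[sample(nrow(sim$bundle$civil)), ]
  ms2 <- suppressWarnings(match_controls(
    perm_cases, perm_persons, sim$bundle$psychiatric, def, cfg))
  expect_equal(as.data.frame(ms1$sets), as.data.frame(ms2$sets),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(ms1$controls[order(set_id, control_id)]),
               as.data.frame(ms2$controls[order(set_id, control_id)]),
               ignore_attr = TRUE)
  expect_true(all(ms1$sets$n_controls <= 10L))
  # a different seed changes at least one sampled control set
  cfg2 <- study_config(seed = 99L)
  ms3 <- suppressWarnings(match_controls(
    cases, sim$bundle$civil, sim$bundle$psychiatric, def, cfg2))
  expect_false(identical(ms1$controls$control_id, ms3$controls$control_id))
})

test_that("matched cohorts across the whole catalogue satisfy all invariants", {
  sim <- small_sim()
  ms <- small_cohort()
  chk <- check_matched_sets(ms, sim$bundle$civil, sim$bundle$psychiatric,
                            default_disorder_catalogue(),
                            study_config(seed = 42L))
  expect_true(all(chk$all_ok))
  # one set per case per disorder
  expect_identical(anyDuplicated(ms$sets[, .(disorder_name, case_id)]), 0L)
})

test_that("the 'ever disorder-free' config switch tightens eligibility", {
  catal <- default_disorder_catalogue()
  def <- catal[catal$disorder_name == "schizophrenia", ]
  idx <- as.Date("2010-06-01")
  persons <- rbind(civil_row("CASE", "female", "1980-03-15"),
                   civil_row("LATER", "female", "1980-03-20"),
                   civil_row("CLEAN", "female", "1980-03-25"))
  dx <- data.table::data.table(
    person_id = c("CASE", "LATER"),
    event_date = c(idx, as.Date("2014-01-01")),
    icd10_code = "F20", contact_type = "inpatient")
  cases <- identify_cases(dx, persons, def, cfg)[person_id == "CASE"]
  ms_at <- suppressWarnings(match_controls(cases, persons, dx, def, cfg))
  expect_setequal(ms_at$controls$control_id, c("LATER", "CLEAN"))
  cfg_ever <- study_config(seed = 5L, control_history = "ever")
  ms_ever <- suppressWarnings(match_controls(cases, persons, dx, def, cfg_ever))
  expect_identical(ms_ever$controls$control_id, "CLEAN")
})
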