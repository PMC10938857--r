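test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(n_persons = 0), class = "regcost_param_error")
  bad_h <- default_diagnosis_hazards(); bad_h[1L] <- 1.5
  expect_error(sim_params(diagnosis_hazards = bad_h),
               class = "regcost_param_error")
  expect_error(sim_params(disorder_effects = uniform_disorder_effects(decay = 0)),
               class = "regcost_param_error")
  expect_error(sim_params(disorder_effects = uniform_disorder_effects(
    income_decrement = -1)), class = "regcost_param_error")
  expect_error(sim_params(female_share = 1.2), class = "regcost_param_error")
})

test_that("zero hazards produce no psychiatric events and no cases", {
  p <- sim_params(n_persons = 300L, seed = 2L,
                  diagnosis_hazards = default_diagnosis_hazards() * 0)
  sim <- simulate_registers(p)
  expect_identical(nrow(sim$bundle$psychiatric), 0L)
  expect_identical(nrow(sim$ground_truth$cases), 0L)
  catal <- default_disorder_catalogue()
  for (i in seq_len(nrow(catal))) {
    expect_identical(nrow(identify_cases(
      sim$bundle$psychiatric, sim$bundle$civil, catal[i], study_config())), 0L)
  }
})

test_that("simulation is byte-deterministic under a fixed seed", {
  p <- sim_params(n_persons = 500L, seed = 123L)
  s1 <- simulate_registers(p)
  s2 <- simulate_registers(p)
  expect_identical(s1$bundle, s2$bundle)
  expect_identical(s1$ground_truth$injections, s2$ground_truth$injections)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_register_bundle(s1$bundle, d1)
  write_register_bundle(s2$bundle, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  s3 <- simulate_registers(sim_params(n_persons = 500L, seed = 124L))
  expect_false(identical(s1$bundle$civil, s3$bundle$civil))
})

test_that("no event or money row falls outside a person's residency", {
  sim <- small_sim()
  civ <- sim$bundle$civil
  res_end <- pmin(
    data.table::fifelse(is.na(civ$death_date), as.Date("2017-04-23"),
                        civ$death_date),
    data.table::fifelse(is.na(civ$emigration_date), as.Date("2017-04-23"),
                        civ$emigration_date))
  res_start <- pmax(civ$birth_date,
                    data.table::fifelse(is.na(civ$immigration_date),
                                        civ$birth_date, civ$immigration_date))
  lookup_start <- setNames(res_start, civ$person_id)
  lookup_end <- setNames(res_end, civ$person_id)

  psy <- sim$bundle$psychiatric
  expect_true(all(psy$event_date >= lookup_start[psy$person_id]))
  expect_true(all(psy$event_date < lookup_end[psy$person_id]))

  for (nm in c("drg_costs", "prescriptions", "primary_care", "income")) {
    tbl <- sim$bundle[[nm]]
    ys <- as.Date(sprintf("%d-01-01", tbl$year))
    ye <- as.Date(sprintf("%d-01-01", tbl$year + 1L))
    overlap <- pmin(lookup_end[tbl$person_id], ye) >
      pmax(lookup_start[tbl$person_id], ys)
    expect_true(all(overlap), info = nm)
    expect_true(all(tbl$year >= 2004L & tbl$year <= 2017L), info = nm)
  }
})

test_that("expected excess decays geometrically by years since diagnosis", {
  p <- sim_params(n_persons = 2000L, seed = 31L,
                  disorder_effects = uniform_disorder_effects(
                    excess_psych = 1000, excess_somatic = 0,
                    income_decrement = 0, transfer_increment = 0, decay = 0.8))
  sim <- simulate_registers(p)
  ee <- expected_estimands(p, sim$ground_truth)
  prof <- ee$profile[disorder_name == "major depressive disorder" &
                       component == "psych_cost"]
  prof <- prof[order(offset_years)]
  # the generative model forces expected year-k excess = 0.8^k x year-0
  ratios <- prof$expected[-1L] / prof$expected[-nrow(prof)]
  expect_equal(ratios[1:6], rep(0.8, 6), tolerance = 1e-9)
  expect_equal(prof$expected[1L], 1000, tolerance = 1e-9)
})

test_that("zero effects give zero expected excess for every disorder", {
  p <- sim_params(n_persons = 1000L, seed = 5L,
                  disorder_effects = zero_disorder_effects())
  sim <- simulate_registers(p)
  ee <- expected_estimands(p, sim$ground_truth)
  expect_true(all(abs(ee$per_case$expected) < 1e-12))
  expect_true(all(abs(ee$nationwide$expected) < 1e-12))
})

test_that("injected psychiatric excess is recovered by the matched design", {
  # moderate scale Monte-Carlo: constant 3000/case-year, no decay
  p <- sim_params(n_persons = 8000L, seed = 9L,
                  disorder_effects = uniform_disorder_effects(
                    excess_psych = 3000, excess_somatic = 0,
                    income_decrement = 0, transfer_increment = 0, decay = 1))
  sim <- simulate_registers(p)
  cfg <- study_config(seed = 9L)
  ms <- suppressWarnings(build_matched_cohort(
    sim$bundle$civil, sim$bundle$psychiatric, default_disorder_catalogue(), cfg))
  panels <- build_cost_panels(sim$bundle, cfg)
  est <- aggregate_estimates(ms, panels, NULL, cfg)
  got <- est[disorder_name == "any mental disorder" & stratum == "overall" &
               measure == "per_case_annual" & cost_kind == "excess" &
               component == "psych_cost"]
  ee <- expected_estimands(p, sim$ground_truth, cfg, matched_sets = ms)
  truth <- ee$per_case[disorder_name == "any mental disorder" &
                         component == "psych_cost"]$expected
  expect_lt(abs(got$value - truth), 3 * got$mc_se)
  expect_lt(abs(got$value / truth - 1), 0.10)
  # without decay the conditional truth is close to the injected 3000 minus
  # control contamination; it must stay within a few percent of nominal
  expect_lt(abs(truth / 3000 - 1), 0.10)
})
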