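test_that("set-level excess is case value minus weighted control mean", {
  fx <- toy_matched_fixture(case_psych = 100, control_psych = c(30, 50),
                            year = 2010L)
  v <- excess_by_year(fx$ms, fx$panels, "psych_cost", 2010L)
  expect_equal(as.numeric(v["toy disorder"]), 100 - 40)
  expect_error(excess_by_year(fx$ms, fx$panels, "no_such", 2010L),
               class = "regcost_component_error")

  # identical case and control panels: zero excess in every component
  fx0 <- toy_matched_fixture(case_psych = 77, control_psych = c(77, 77))
  for (comp in c("psych_cost", "combined_healthcare_cost", "personal_income")) {
    expect_equal(as.numeric(excess_by_year(fx0$ms, fx0$panels, comp, 2010L)), 0)
  }

  # a constant shift applied to everyone leaves the excess unchanged
  fx1 <- toy_matched_fixture(case_psych = 100 + 500,
                             control_psych = c(30, 50) + 500)
  expect_equal(as.numeric(excess_by_year(fx1$ms, fx1$panels, "psych_cost", 2010L)),
               60)
})

test_that("per-case, nationwide and per-capita measures reconcile", {
  ms <- small_cohort()
  panels <- small_panels()
  cfg <- study_config(seed = 42L)
  den <- compute_population_denominators(small_sim()$bundle$civil)
  est <- aggregate_estimates(ms, panels, den, cfg)
  duration <- regcost:::study_duration_years(cfg)

  wide <- data.table::dcast(
    est[stratum_type == "overall"],
    disorder_name + cost_kind + component + n_case_person_years ~ measure,
    value.var = "value")
  # per_case x (case person-years / study years) == nationwide
  expect_equal(wide$per_case_annual * wide$n_case_person_years / duration,
               wide$nationwide_annual, tolerance = 1e-9)
  # per_capita == nationwide / total population denominator
  expect_equal(wide$per_capita_annual, wide$nationwide_annual / sum(den$count),
               tolerance = 1e-9)
})

test_that("sex and age-band strata sum exactly to the overall value", {
  est <- aggregate_estimates(small_cohort(), small_panels(), NULL,
                             study_config(seed = 42L))
  nat <- est[measure == "nationwide_annual"]
  for (st in c("sex", "age_band")) {
    sums <- nat[stratum_type == st,
                .(value = sum(value)),
                by = .(disorder_name, cost_kind, component)]
    overall <- nat[stratum_type == "overall",
                   .(disorder_name, cost_kind, component, overall = value)]
    m <- merge(sums, overall, by = c("disorder_name", "cost_kind", "component"))
    expect_equal(m$value, m$overall, tolerance = 1e-9, info = st)
    # person-years partition too
    pys <- est[measure == "per_case_annual" & stratum_type == st &
                 component == "psych_cost" & cost_kind == "excess",
               .(py = sum(n_case_person_years)), by = disorder_name]
    pyo <- est[measure == "per_case_annual" & stratum_type == "overall" &
                 component == "psych_cost" & cost_kind == "excess",
               .(disorder_name, py0 = n_case_person_years)]
    mp <- merge(pys, pyo, by = "disorder_name")
    expect_equal(mp$py, mp$py0, tolerance = 1e-9, info = st)
  }
})

test_that("every estimate equals a brute-force recomputation on a toy bundle", {
  sim <- oracle_sim()
  ms <- oracle_cohort()
  panels <- oracle_panels()
  cfg <- study_config(seed = 11L)
  den <- compute_population_denominators(sim$bundle$civil)
  est <- aggregate_estimates(ms, panels, den, cfg)

  for (comp in c("psych_cost", "combined_healthcare_cost", "personal_income",
                 "transfers_total")) {
    oracle <- oracle_estimates(ms, panels, den, comp, cfg)
    got <- est[component == comp]
    for (i in seq_len(nrow(oracle))) {
      o <- oracle[i, ]
      sub <- got[disorder_name == o$disorder_name &
                   stratum_type == o$stratum_type & stratum == o$stratum]
      pick <- function(m, k) sub[measure == m & cost_kind == k]$value
      expect_equal(pick("nationwide_annual", "absolute"), o$nationwide_abs,
                   tolerance = 1e-9)
      expect_equal(pick("nationwide_annual", "excess"), o$nationwide_exc,
                   tolerance = 1e-9)
      expect_equal(pick("per_case_annual", "absolute"), o$per_case_abs,
                   tolerance = 1e-9)
      expect_equal(pick("per_case_annual", "excess"), o$per_case_exc,
                   tolerance = 1e-9)
      if (length(pick("per_capita_annual", "excess"))) {
        expect_equal(pick("per_capita_annual", "excess"), o$per_capita_exc,
                     tolerance = 1e-9)
      }
      expect_equal(sub$n_case_person_years[1L], o$n_py, tolerance = 1e-9)
    }
  }
})

test_that("years-since-diagnosis profile respects censoring and offsets", {
  # case diagnosed 2016-06-01: contributes offset 0 and a fractional offset 1
  fx <- toy_matched_fixture(case_psych = 10, control_psych = c(0, 0),
                            year = 2016L)
  fx$ms$sets$index_date <- as.Date("2016-06-01")
  p17 <- data.table::copy(fx$panels)[year == 2016L]
  p17[, year := 2017L]
  p17[, py := regcost:::year_fraction(as.Date("2017-01-01"),
                                      as.Date("2017-04-23"), 2017L)]
  panels <- rbind(fx$panels, p17)
  prof <- years_since_diagnosis_profile(fx$ms, panels)
  pp <- prof[component == "psych_cost"]
  expect_setequal(pp$offset_years, c(0L, 1L))
  py1 <- pp[offset_years == 1L]$n_case_person_years
  expect_equal(py1, 112 / 365, tolerance = 1e-9)
  # offset 0 person-time runs from the index date to the year end
  expect_equal(pp[offset_years == 0L]$n_case_person_years,
               as.numeric(as.Date("2017-01-01") - as.Date("2016-06-01")) / 366,
               tolerance = 1e-9)

  # profile only uses cases identified 2004 onwards
  fx$ms$sets$index_date <- as.Date("2003-06-01")
  expect_error(years_since_diagnosis_profile(fx$ms, panels),
               class = "regcost_estimation_error")
})

test_that("null simulation yields excess estimates consistent with zero", {
  # small-scale version of the null-recovery property
  p <- sim_params(n_persons = 4000L, seed = 17L,
                  disorder_effects = zero_disorder_effects())
  sim <- simulate_registers(p)
  cfg <- study_config(seed = 17L)
  ms <- suppressWarnings(build_matched_cohort(
    sim$bundle$civil, sim$bundle$psychiatric, default_disorder_catalogue(), cfg))
  panels <- build_cost_panels(sim$bundle, cfg)
  est <- aggregate_estimates(ms, panels, NULL, cfg)
  got <- est[stratum == "overall" & measure == "per_case_annual" &
               cost_kind == "excess" & disorder_name == "any mental disorder" &
               component %in% c("combined_healthcare_cost", "personal_income",
                                "transfers_total")]
  expect_true(all(abs(got$value) < 3 * got$mc_se))
})
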