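test_that("deflation to 2017 Euro: identity year, linearity, hand example", {
  # identity for 2017 with unit exchange rate
  d1 <- deflator_table(c("2017" = 100), fx_rate_2017 = 1)
  expect_equal(to_eur2017(500, 2017L, d1), 500)
  # two-step rule: 1000 * 1.10 / 7.5
  d2 <- deflator_table(c("2010" = 100, "2017" = 110), fx_rate_2017 = 7.5)
  expect_equal(to_eur2017(1000, 2010L, d2), 1000 * 1.10 / 7.5)
  # linearity on random draws
  set.seed(1)
  a <- runif(50, 0, 1e5); b <- runif(50, 0, 1e5)
  yrs <- sample(2004:2017, 50, replace = TRUE)
  d <- default_deflator_table()
  expect_equal(to_eur2017(a + b, yrs, d),
               to_eur2017(a, yrs, d) + to_eur2017(b, yrs, d))
  expect_equal(to_eur2017(1, 2017L, d), 1 / d$fx_rate_2017)
  expect_error(to_eur2017(1, 1999L, d), "no deflator",
               class = "regcost_deflator_error")
})

test_that("subsidised prescription cost is service minus out-of-pocket", {
  civ <- civil_row("X1")
  flat <- setNames(rep(100, 14), 2004:2017)
  d1 <- deflator_table(flat, fx_rate_2017 = 1)
  bundle <- list(
    civil = civ,
    psychiatric = data.table::data.table(
      person_id = character(), event_date = as.Date(character()),
      icd10_code = character(), contact_type = character()),
    drg_costs = data.table::data.table(
      person_id = character(), year = integer(), category = character(),
      amount_nominal = numeric()),
    prescriptions = data.table::data.table(
      person_id = "X1", year = 2010L, service_cost_nominal = 300,
      out_of_pocket_nominal = 120),
    primary_care = data.table::data.table(
      person_id = character(), year = integer(), provider_type = character(),
      amount_nominal = numeric()),
    income = data.table::data.table(
      person_id = character(), year = integer(),
      personal_income_nominal = numeric())
  )
  for (tc in regcost:::TRANSFER_COLUMNS) bundle$income[[tc]] <- numeric()
  p <- assemble_annual_costs("X1", 2010L, bundle, study_config(), d1)
  expect_equal(p$rx_subsidised_cost, 180)
  expect_equal(p$rx_out_of_pocket_cost, 120)
  expect_equal(p$combined_healthcare_cost, 180)  # out-of-pocket excluded

  # a person-year without any register rows still yields a panel of zeros
  p0 <- assemble_annual_costs("X1", 2011L, bundle, study_config(), d1)
  expect_identical(nrow(p0), 1L)
  expect_true(all(unlist(p0[, regcost:::COST_COMPONENTS, with = FALSE]) == 0))

  # out-of-pocket above service cost is floored at zero with a warning
  bundle$prescriptions$out_of_pocket_nominal <- 400
  expect_warning(p2 <- assemble_annual_costs("X1", 2010L, bundle,
                                             study_config(), d1),
                 "floored")
  expect_equal(p2$rx_subsidised_cost, 0)

  # years outside the follow-up window are refused
  d0 <- deflator_table(c(flat, "2003" = 99), 1)
  expect_error(assemble_annual_costs("X1", 2003L, bundle, study_config(), d0),
               class = "regcost_window_error")
})

test_that("panel additivity and person-time invariants hold on simulated data", {
  panels <- small_panels()
  expect_equal(panels$combined_healthcare_cost,
               panels$psych_cost + panels$somatic_cost +
                 panels$rx_subsidised_cost + panels$primary_care_cost)
  expect_equal(panels$transfers_total,
               rowSums(panels[, regcost:::TRANSFER_COLUMNS, with = FALSE]))
  expect_true(all(panels$py > 0 & panels$py <= 1))
  expect_true(all(panels$year %in% 2004:2017))
  hc <- c("psych_cost", "somatic_cost", "rx_subsidised_cost",
          "rx_out_of_pocket_cost", "primary_care_cost")
  expect_true(all(as.matrix(panels[, hc, with = FALSE]) >= 0))

  # no panel outside a follow-up window, and one panel per window-year
  w <- followup_windows(small_sim()$bundle$civil, study_config(seed = 42L))
  key <- paste(panels$person_id, panels$year)
  wyears <- w[, .(year = seq(data.table::year(start),
                             data.table::year(end - 1L))), by = person_id]
  expect_setequal(key, paste(wyears$person_id, wyears$year))
})

test_that("nominal amounts are conserved from registers to panels", {
  bundle <- small_sim()$bundle
  cfg <- study_config(seed = 42L)
  panels <- small_panels()
  defl <- default_deflator_table()
  f <- to_eur2017(1, panels$year, defl)
  # every simulated register row lies inside a follow-up window, so register
  # totals and (re-nominalised) panel totals must agree category by category
  expect_equal(sum(panels$psych_cost / f),
               bundle$drg_costs[category == "psych_drg", sum(amount_nominal)])
  expect_equal(sum(panels$somatic_cost / f),
               bundle$drg_costs[category == "somatic_drg", sum(amount_nominal)])
  expect_equal(sum(panels$rx_out_of_pocket_cost / f),
               sum(bundle$prescriptions$out_of_pocket_nominal))
  expect_equal(sum(panels$primary_care_cost / f),
               sum(bundle$primary_care$amount_nominal))
  expect_equal(sum(panels$personal_income / f),
               sum(bundle$income$personal_income_nominal))
})
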