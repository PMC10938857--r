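# Shared fixtures. Large simulations are cached so several test files can
# reuse the same bundle without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

ACCEPTANCE_SEED <- 1L

# small bundle with the default (non-zero) effects, for unit tests
small_sim <- function() {
  cached("small_sim", simulate_registers(
    sim_params(n_persons = 800L, seed = 42L)))
}

small_cohort <- function() {
  cached("small_cohort", {
    sim <- small_sim()
    suppressWarnings(build_matched_cohort(
      sim$bundle$civil, sim$bundle$psychiatric,
      default_disorder_catalogue(), study_config(seed = 42L)))
  })
}

small_panels <- function() {
  cached("small_panels", suppressWarnings(
    build_cost_panels(small_sim()$bundle, study_config(seed = 42L))))
}

# toy bundle <= 100 persons with inflated hazards, for oracle equivalence
oracle_sim <- function() {
  cached("oracle_sim", simulate_registers(sim_params(
    n_persons = 100L, seed = 11L,
    diagnosis_hazards = pmin(default_diagnosis_hazards() * 30, 0.05))))
}

oracle_cohort <- function() {
  cached("oracle_cohort", {
    sim <- oracle_sim()
    suppressWarnings(build_matched_cohort(
      sim$bundle$civil, sim$bundle$psychiatric,
      default_disorder_catalogue(), study_config(seed = 11L)))
  })
}

oracle_panels <- function() {
  cached("oracle_panels", suppressWarnings(
    build_cost_panels(oracle_sim()$bundle, study_config(seed = 11L))))
}

# n = 20,000 bundle with all disorder effects zero: shared by the matching
# validity and null-recovery acceptance tests
null_sim20 <- function() {
  cached("null_sim20", simulate_registers(sim_params(
    n_persons = 20000L, seed = ACCEPTANCE_SEED,
    disorder_effects = zero_disorder_effects())))
}

null_cohort20 <- function() {
  cached("null_cohort20", {
    sim <- null_sim20()
    suppressWarnings(build_matched_cohort(
      sim$bundle$civil, sim$bundle$psychiatric,
      default_disorder_catalogue(), study_config(seed = ACCEPTANCE_SEED)))
  })
}

null_panels20 <- function() {
  cached("null_panels20", suppressWarnings(
    build_cost_panels(null_sim20()$bundle,
                      study_config(seed = ACCEPTANCE_SEED))))
}

# hand-built one-set fixture: case P1 with two controls, complete years;
# every component 0 except chosen values for combined healthcare inputs
toy_matched_fixture <- function(case_psych = 100, control_psych = c(30, 50),
                                year = 2010L) {
  sets <- data.table::data.table(
    set_id = "toy#1", disorder_name = "toy disorder", case_id = "P1",
    case_sex = "female", case_birth = as.Date("1980-01-01"),
    index_date = as.Date(sprintf("%d-01-01", year)),
    window_start = as.Date("2004-01-01"), window_end = as.Date("2017-04-23"),
    n_controls = length(control_psych))
  controls <- data.table::data.table(
    set_id = "toy#1", control_id = paste0("C", seq_along(control_psych)))
  ms <- structure(list(sets = sets, controls = controls),
                  class = "matched_sets")
  comp0 <- setNames(as.list(rep(0, length(regcost:::COST_COMPONENTS))),
                    regcost:::COST_COMPONENTS)
  row <- function(pid, psych) {
    out <- data.table::as.data.table(
      c(list(person_id = pid, year = year, py = 1), comp0))
    out$psych_cost <- psych
    out$combined_healthcare_cost <- psych
    out
  }
  panels <- data.table::rbindlist(
    c(list(row("P1", case_psych)),
      lapply(seq_along(control_psych),
             function(i) row(paste0("C", i), control_psych[i]))))
  list(ms = ms, panels = panels)
}

# minimal hand-written civil register rows
civil_row <- function(person_id = "X1", sex = "female",
                      birth_date = "1980-06-15", immigration_date = NA,
                      emigration_date = NA, death_date = NA) {
  data.table::data.table(
    person_id = person_id, sex = sex, birth_date = as.Date(birth_date),
    immigration_date = as.Date(immigration_date),
    emigration_date = as.Date(emigration_date),
    death_date = as.Date(death_date))
}
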