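# Synthetic register generator with known ground truth.
#
# Discrete-time simulation at yearly resolution; event dates are drawn
# uniformly within the eligible part of the year. Disorder-attributable
# effects are injected per case person-year and decay geometrically with the
# number of calendar years since the diagnosis year, so the expected year-k
# excess is decay^k times the year-0 excess by construction. All effect and
# baseline magnitudes are specified in 2017 Euro; the generator converts them
# to nominal local currency when writing the registers, which is exactly what
# the costing module undoes.

DX_HORIZON_START <- as.Date("1995-01-01")
COST_HORIZON_START <- as.Date("2004-01-01")
DATA_CUT <- as.Date("2017-04-23")

#' Default per-disorder annual diagnosis hazards
#'
#' First-diagnosis hazards per person-year at risk (alive, resident, at or
#' above the assumed onset age, not yet diagnosed), graded over
#' 2e-5..1.5e-3 per year to give realistic relative frequencies of
#' hospital-treated disorders in a Scandinavian-style population: common mood
#' and anxiety disorders at the top, cocaine-use and conduct disorders rare.
#'
#' @return named numeric vector over the 18 disorder names.
#' @export
default_diagnosis_hazards <- function() {
  c("major depressive disorder" = 1.5e-3,
    "anxiety disorders"         = 1.0e-3,
    "personality disorders"     = 6.5e-4,
    "ADHD"                      = 5.5e-4,
    "alcohol-use disorder"      = 4.5e-4,
    "autism spectrum disorders" = 3.5e-4,
    "schizophrenia"             = 3.0e-4,
    "bipolar disorder"          = 2.2e-4,
    "intellectual disabilities" = 2.0e-4,
    "cannabis-use disorder"     = 1.5e-4,
    "anorexia nervosa"          = 9.0e-5,
    "dysthymia"                 = 6.0e-5,
    "other drug-use disorders"  = 6.0e-5,
    "opioid-use disorder"       = 5.0e-5,
    "bulimia nervosa"           = 5.0e-5,
    "amphetamine-use disorder"  = 2.5e-5,
    "cocaine-use disorder"      = 2.0e-5,
    "conduct disorders"         = 2.0e-5)[DISORDER_NAMES]
}

#' Disorder-attributable effects
#'
#' `uniform_disorder_effects()` builds an effects table giving every named
#' disorder the same excess psychiatric hospital cost, excess somatic hospital
#' cost, personal-income decrement and public-transfer increment per case-year
#' (2017 Euro), and the same yearly decay factor: in the k-th calendar year
#' after the diagnosis year the injected effect is `decay^k` times the
#' first-year effect, scaled by the case's person-time in that year.
#'
#' @param excess_psych,excess_somatic,income_decrement,transfer_increment
#'   effects in 2017 Euro per case-year, all `>= 0`.
#' @param decay yearly decay factor in `(0, 1]`.
#' @param disorders disorder names (default: the 18 named disorders).
#' @return a `data.table` with one row per disorder.
#' @export
uniform_disorder_effects <- function(excess_psych = 2500,
                                     excess_somatic = 600,
                                     income_decrement = 8000,
                                     transfer_increment = 4000,
                                     decay = 0.85,
                                     disorders = DISORDER_NAMES) {
  data.table(
    disorder_name = disorders,
    excess_psych = excess_psych,
    excess_somatic = excess_somatic,
    income_decrement = income_decrement,
    transfer_increment = transfer_increment,
    decay = decay
  )
}

#' @rdname uniform_disorder_effects
#' @export
zero_disorder_effects <- function(disorders = DISORDER_NAMES) {
  uniform_disorder_effects(0, 0, 0, 0, 1, disorders)
}

default_baselines <- function() {
  list(
    psych   = list(p = 0.006, meanlog = log(2500), sdlog = 1.0),
    somatic = list(p = 0.55,  meanlog = log(700),  sdlog = 1.0),
    rx      = list(p = 0.65,  meanlog = log(220),  sdlog = 1.0,
                   oop_share = c(0.20, 0.45)),
    primary = list(p = 0.85,  meanlog = log(170),  sdlog = 0.7),
    income  = list(participation = 0.88, meanlog = log(34000), sdlog = 0.45),
    transfer_scale = 1.0
  )
}

#' Simulation parameters
#'
#' @param n_persons population size (`>= 1`).
#' @param seed integer seed; identical parameters and seed give a
#'   byte-identical register bundle.
#' @param birth_year_range integer `c(first, last)` birth years, uniform.
#' @param female_share probability of sex `"female"`.
#' @param immigrant_fraction share of persons entering by immigration.
#' @param annual_emigration_prob yearly emigration probability (adults).
#' @param mortality `c(rate, slope)` of the Gompertz-type yearly death hazard
#'   `rate * exp(slope * age)`.
#' @param diagnosis_hazards named yearly first-diagnosis hazards per disorder,
#'   all in `[0, 1]`.
#' @param disorder_effects effects table (see [uniform_disorder_effects()]).
#' @param baselines baseline cost/income distribution settings; see
#'   `regcost:::default_baselines()`. Baselines are right-skewed lognormal
#'   draws with many exact zeros, scaled by within-year exposure.
#' @param repeat_contact_rate yearly rate of additional psychiatric contacts
#'   after a first diagnosis (register realism; does not affect estimands).
#' @param catalogue disorder catalogue used to emit ICD-10 codes.
#' @param deflator a [deflator_table()] used to restate the simulated 2017-Euro
#'   amounts in nominal local currency per register year.
#' @return a list with class `sim_params`.
#' @export
sim_params <- function(n_persons = 20000L,
                       seed = 1L,
                       birth_year_range = c(1955L, 2000L),
                       female_share = 0.5,
                       immigrant_fraction = 0.05,
                       annual_emigration_prob = 0.002,
                       mortality = c(rate = 5e-5, slope = 0.085),
                       diagnosis_hazards = default_diagnosis_hazards(),
                       disorder_effects = uniform_disorder_effects(),
                       baselines = default_baselines(),
                       repeat_contact_rate = 0.25,
                       catalogue = default_disorder_catalogue(),
                       deflator = default_deflator_table()) {
  if (n_persons < 1L) abort("n_persons must be >= 1", class = "regcost_param_error")
  if (any(diagnosis_hazards < 0 | diagnosis_hazards > 1) ||
      anyNA(diagnosis_hazards)) {
    abort("diagnosis hazards must lie in [0, 1]", class = "regcost_param_error")
  }
  missing_dis <- setdiff(catalogue[is_aggregate == FALSE]$disorder_name,
                         names(diagnosis_hazards))
  if (length(missing_dis)) {
    abort(paste0("no diagnosis hazard for: ", paste(missing_dis, collapse = ", ")),
          class = "regcost_param_error")
  }
  eff <- as.data.table(disorder_effects)
  if (any(eff$decay <= 0 | eff$decay > 1)) {
    abort("decay factors must lie in (0, 1]", class = "regcost_param_error")
  }
  if (any(eff$excess_psych < 0 | eff$excess_somatic < 0 |
            eff$income_decrement < 0 | eff$transfer_increment < 0)) {
    abort("disorder effects must be >= 0", class = "regcost_param_error")
  }
  if (female_share < 0 || female_share > 1 ||
      immigrant_fraction < 0 || immigrant_fraction > 1 ||
      annual_emigration_prob < 0 || annual_emigration_prob > 1) {
    abort("probabilities must lie in [0, 1]", class = "regcost_param_error")
  }
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    birth_year_range = as.integer(birth_year_range),
    female_share = female_share, immigrant_fraction = immigrant_fraction,
    annual_emigration_prob = annual_emigration_prob,
    mortality = mortality, diagnosis_hazards = diagnosis_hazards,
    disorder_effects = eff, baselines = baselines,
    repeat_contact_rate = repeat_contact_rate,
    catalogue = catalogue, deflator = deflator
  ), class = "sim_params")
}

simulate_persons <- function(p) {
  n <- p$n_persons
  ids <- sprintf("P%07d", seq_len(n))
  sex <- fifelse(runif(n) < p$female_share, "female", "male")
  b0 <- year_start(p$birth_year_range[1L])
  b1 <- year_start(p$birth_year_range[2L] + 1L)
  birth <- runif_date(rep(b0, n), b1)

  imm <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  is_imm <- runif(n) < p$immigrant_fraction
  lo <- birth[is_imm] + 365L
  hi <- pmin(birth[is_imm] + 45L * 365L, as.Date("2017-01-01"))
  ok <- lo < hi
  imm[which(is_imm)[ok]] <- runif_date(lo[ok], hi[ok])

  death <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  emig <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  m0 <- p$mortality[[1L]]
  m1 <- p$mortality[[2L]]
  far_past <- as.Date("1900-01-01")
  for (y in 1995:2017) {
    age <- y - year(birth)
    active <- is.na(death) & is.na(emig) & age >= 0 &
      (is.na(imm) | year(imm) <= y)
    p_die <- pmin(0.5, m0 * exp(m1 * pmax(age, 0)))
    die <- active & runif(n) < p_die
    if (any(die)) {
      lo <- pmax(year_start(y), birth[die],
                 fifelse(is.na(imm[die]), far_past, imm[die]))
      death[die] <- runif_date(lo, rep(year_start(y + 1L), sum(die)))
    }
    emi <- active & !die & age >= 18 & runif(n) < p$annual_emigration_prob
    if (any(emi)) {
      lo <- pmax(year_start(y), fifelse(is.na(imm[emi]), far_past, imm[emi]))
      emig[emi] <- runif_date(lo, rep(year_start(y + 1L), sum(emi)))
    }
  }
  data.table(person_id = ids, sex = sex, birth_date = birth,
             immigration_date = imm, emigration_date = emig,
             death_date = death)
}

# residency interval used for event/cost generation (half-open)
residency_interval <- function(civil) {
  rs <- pmax(civil$birth_date,
             fifelse(is.na(civil$immigration_date), civil$birth_date,
                     civil$immigration_date))
  re <- pmin(
    fifelse(is.na(civil$death_date), DATA_CUT, civil$death_date),
    fifelse(is.na(civil$emigration_date), DATA_CUT, civil$emigration_date),
    DATA_CUT
  )
  list(start = rs, end = re)
}

simulate_first_diagnoses <- function(p, civil) {
  res <- residency_interval(civil)
  n <- nrow(civil)
  named <- p$catalogue[is_aggregate == FALSE]
  out <- vector("list", nrow(named))
  for (i in seq_len(nrow(named))) {
    def <- named[i]
    hz <- p$diagnosis_hazards[[def$disorder_name]]
    if (hz == 0) next
    onset <- civil$birth_date + round(def$earliest_onset_age * 365.25)
    undiag <- rep(TRUE, n)
    rows <- vector("list", 23L)
    for (y in 1995:2017) {
      lo <- pmax(year_start(y), onset, res$start, DX_HORIZON_START)
      hi <- pmin(year_start(y + 1L), res$end)
      frac <- pmax(as.numeric(hi - lo), 0) / days_in_year(y)
      hit <- undiag & runif(n) < hz * frac
      if (any(hit)) {
        rows[[y - 1994L]] <- data.table(
          person_id = civil$person_id[hit],
          disorder_name = def$disorder_name,
          dx_date = runif_date(lo[hit], hi[hit])
        )
        undiag[hit] <- FALSE
      }
    }
    out[[i]] <- rbindlist(rows)
  }
  dx <- rbindlist(out)
  if (nrow(dx) == 0L) {
    dx <- data.table(person_id = character(), disorder_name = character(),
                     dx_date = as.Date(character()))
  }
  setorder(dx, person_id, disorder_name)
  dx
}

sim_icd_code <- function(defs_by_name, disorder, n) {
  if (n == 0L) return(character())
  codes <- defs_by_name[[disorder]]
  base <- codes[1L + floor(runif(n) * length(codes))]
  dotted <- grepl(".", base, fixed = TRUE)
  digit <- as.character(floor(runif(n) * 10))
  decorate <- runif(n) < 0.5
  fifelse(decorate & dotted, paste0(base, digit),
          fifelse(decorate, paste0(base, ".", digit), base))
}

sim_contact_type <- function(n) {
  c("inpatient", "outpatient", "emergency")[
    1L + findInterval(runif(n), c(0.25, 0.90))]
}

simulate_psychiatric_register <- function(p, civil, dx) {
  if (nrow(dx) == 0L) {
    return(data.table(person_id = character(),
                      event_date = as.Date(character()),
                      icd10_code = character(), contact_type = character()))
  }
  defs_by_name <- setNames(p$catalogue$icd10_codes, p$catalogue$disorder_name)
  first_rows <- dx[, .(person_id, event_date = dx_date,
                       icd10_code = sim_icd_code(defs_by_name, disorder_name[1L], .N),
                       contact_type = sim_contact_type(.N)),
                   by = disorder_name][, disorder_name := NULL]
  res <- residency_interval(civil)
  resdt <- data.table(person_id = civil$person_id,
                      resid_start = res$start, resid_end = res$end)
  grid <- dx[resdt, on = "person_id", nomatch = NULL][
    , .(year = year(dx_date):2017L), by = .(person_id, disorder_name, dx_date,
                                            resid_start, resid_end)]
  grid[, `:=`(lo = pmax(year_start(year), dx_date, resid_start),
              hi = pmin(year_start(year + 1L), resid_end))]
  grid[, frac := pmax(as.numeric(hi - lo), 0) / days_in_year(year)]
  grid <- grid[frac > 0]
  grid[, n_rep := rpois(.N, p$repeat_contact_rate * frac)]
  reps <- grid[n_rep > 0, .(person_id, disorder_name, lo, hi, n_rep)]
  rep_rows <- if (nrow(reps)) {
    expanded <- reps[rep(seq_len(.N), n_rep)]
    expanded[, event_date := runif_date(lo, hi)]
    expanded[, icd10_code := sim_icd_code(defs_by_name, disorder_name[1L], .N),
             by = disorder_name]
    expanded[, .(person_id, event_date, icd10_code,
                 contact_type = sim_contact_type(.N))]
  } else NULL
  psy <- rbindlist(list(first_rows, rep_rows), use.names = TRUE)
  setorder(psy, person_id, event_date, icd10_code)
  psy[]
}

lnorm_draws <- function(n, use_p, meanlog, sdlog, scale) {
  use <- runif(n) < use_p
  amt <- numeric(n)
  k <- sum(use)
  if (k) amt[use] <- rlnorm(k, meanlog, sdlog) * scale[use]
  amt
}

# person-year baseline grid in 2017 Euro (exposure-scaled)
simulate_baseline_grid <- function(p, civil) {
  res <- residency_interval(civil)
  base <- data.table(person_id = civil$person_id, sex = civil$sex,
                     birth = civil$birth_date,
                     resid_start = pmax(res$start, COST_HORIZON_START),
                     resid_end = res$end)
  grid <- base[, .(year = 2004:2017), by = .(person_id, sex, birth,
                                             resid_start, resid_end)]
  grid[, exposure := year_fraction(resid_start, resid_end, year)]
  grid <- grid[exposure > 0]
  grid[, age := attained_age(birth, year)]
  n <- nrow(grid)
  b <- p$baselines
  grid[, psych_amt := lnorm_draws(n, b$psych$p, b$psych$meanlog,
                                  b$psych$sdlog, exposure)]
  som_mult <- pmax(0.3, 1 + 0.015 * (grid$age - 40)) * grid$exposure
  grid[, somatic_amt := lnorm_draws(n, b$somatic$p, b$somatic$meanlog,
                                    b$somatic$sdlog, som_mult)]
  grid[, rx_service := lnorm_draws(n, b$rx$p, b$rx$meanlog, b$rx$sdlog,
                                   exposure)]
  grid[, rx_oop := rx_service *
         runif(n, b$rx$oop_share[1L], b$rx$oop_share[2L])]
  grid[, primary_amt := lnorm_draws(n, b$primary$p, b$primary$meanlog,
                                    b$primary$sdlog, exposure)]
  work <- grid$age >= 18 & grid$age <= 64
  hump <- pmax(0.15, 1 - ((grid$age - 45) / 35)^2)
  inc_scale <- work * hump * (1 + 0.08 * (grid$sex == "male")) * grid$exposure
  grid[, income_amt := lnorm_draws(n, b$income$participation,
                                   b$income$meanlog, b$income$sdlog, inc_scale)]
  ts <- b$transfer_scale * grid$exposure
  age <- grid$age
  grid[, unemployment_benefits := lnorm_draws(n, 0.07, log(9000), 0.4, ts * work)]
  grid[, social_assistance := lnorm_draws(n, 0.03, log(7000), 0.4, ts * (age >= 18))]
  grid[, state_educational_grants :=
         lnorm_draws(n, 0.30, log(5500), 0.3, ts * (age >= 18 & age <= 25))]
  grid[, housing_benefits := lnorm_draws(n, 0.06, log(2500), 0.4, ts * (age >= 18))]
  grid[, child_youth_benefits :=
         lnorm_draws(n, 0.25, log(1800), 0.3, ts * (age >= 25 & age <= 45))]
  grid[, old_age_pension := lnorm_draws(n, 1.0, log(13000), 0.2, ts * (age >= 65))]
  grid[, disability_pension :=
         lnorm_draws(n, 0.04, log(16000), 0.25, ts * (age >= 30 & age <= 64))]
  grid[, flexi_job := lnorm_draws(n, 0.01, log(12000), 0.3, ts * (age >= 30 & age <= 64))]
  grid[, early_retirement :=
         lnorm_draws(n, 0.20, log(15000), 0.3, ts * (age >= 60 & age <= 64))]
  grid
}

# disorder-attributable injections per case person-year, 2017 Euro
simulate_injections <- function(p, civil, dx) {
  if (nrow(dx) == 0L) {
    return(data.table(person_id = character(), disorder_name = character(),
                      year = integer(), inj_psych = numeric(),
                      inj_somatic = numeric(), inj_income = numeric(),
                      inj_transfer = numeric()))
  }
  res <- residency_interval(civil)
  resdt <- data.table(person_id = civil$person_id,
                      resid_start = pmax(res$start, COST_HORIZON_START),
                      resid_end = res$end)
  inj <- dx[resdt, on = "person_id", nomatch = NULL][
    year(dx_date) <= 2017L,
    .(year = max(2004L, year(dx_date)):2017L),
    by = .(person_id, disorder_name, dx_date, resid_start, resid_end)]
  inj[, exposure := year_fraction(pmax(dx_date, resid_start), resid_end, year)]
  inj <- inj[exposure > 0]
  inj[, offset_years := year - year(dx_date)]
  inj <- p$disorder_effects[inj, on = "disorder_name"]
  inj[, `:=`(
    inj_psych = excess_psych * decay^offset_years * exposure,
    inj_somatic = excess_somatic * decay^offset_years * exposure,
    inj_income = income_decrement * decay^offset_years * exposure,
    inj_transfer = transfer_increment * decay^offset_years * exposure
  )]
  inj[, .(person_id, disorder_name, year, inj_psych, inj_somatic,
          inj_income, inj_transfer)]
}

#' Simulate a register bundle with known ground truth
#'
#' Generates a civil register with birth, immigration, emigration and death
#' dates; first psychiatric diagnoses per disorder under the configured
#' hazards, with repeat contacts for register realism; and annual cost, income
#' and transfer rows for every resident person-year of the 2004-2017 register
#' horizon (rows end at the 2017-04-23 data cut, mirroring a register
#' extract). Cases carry injected excess psychiatric and somatic hospital
#' cost, an income decrement (floored so income stays non-negative) and a
#' transfer increment (booked as disability pension), each decaying by
#' `decay^k` in the k-th calendar year after diagnosis. The realised injected
#' amounts per case person-year are returned as ground truth.
#'
#' Identical parameters and seed reproduce the bundle byte for byte; no
#' cost, income or diagnosis row falls outside its person's alive-and-resident
#' interval.
#'
#' @param params a [sim_params()].
#' @return a list with elements `bundle` (a `register_bundle`) and
#'   `ground_truth` (class `ground_truth`: `$persons`, `$cases`,
#'   `$injections`, `$effects`, `$params`).
#' @export
simulate_registers <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)

  civil <- simulate_persons(params)
  dx <- simulate_first_diagnoses(params, civil)
  psychiatric <- simulate_psychiatric_register(params, civil, dx)
  grid <- simulate_baseline_grid(params, civil)
  inj <- simulate_injections(params, civil, dx)

  inj_py <- inj[, .(inj_psych = sum(inj_psych), inj_somatic = sum(inj_somatic),
                    inj_income = sum(inj_income),
                    inj_transfer = sum(inj_transfer)),
                by = .(person_id, year)]
  grid <- inj_py[grid, on = c("person_id", "year")]
  for (col in c("inj_psych", "inj_somatic", "inj_income", "inj_transfer")) {
    set(grid, which(is.na(grid[[col]])), col, 0)
  }
  grid[, psych_amt := psych_amt + inj_psych]
  grid[, somatic_amt := somatic_amt + inj_somatic]
  grid[, disability_pension := disability_pension + inj_transfer]
  # income decrement cannot push income below zero; realised loss is reported
  grid[, inj_income_real := pmin(income_amt, inj_income)]
  grid[, income_amt := income_amt - inj_income_real]

  # scale back per-disorder realised income injections where the floor bound
  shrink <- grid[inj_income > 0,
                 .(person_id, year, shrink = inj_income_real / inj_income)]
  inj <- shrink[inj, on = c("person_id", "year")]
  inj[is.na(shrink), shrink := 1]
  inj[, inj_income := inj_income * shrink]
  inj[, shrink := NULL]

  grid[, nf := 1 / to_eur2017(1, year, params$deflator)]  # EUR 2017 -> nominal

  drg <- rbind(
    grid[psych_amt > 0, .(person_id, year, category = "psych_drg",
                          amount_nominal = round(psych_amt * nf, 2))],
    grid[somatic_amt > 0, .(person_id, year, category = "somatic_drg",
                            amount_nominal = round(somatic_amt * nf, 2))]
  )
  setorder(drg, person_id, year, category)

  rx <- grid[rx_service > 0, .(
    person_id, year,
    service_cost_nominal = round(rx_service * nf, 2),
    out_of_pocket_nominal = round(rx_oop * nf, 2))]
  setorder(rx, person_id, year)

  pc <- grid[primary_amt > 0, .(person_id, year, nf, primary_amt)]
  pc[, provider_type := PRIMARY_CARE_PROVIDERS[
    1L + findInterval(runif(.N), cumsum(c(0.45, 0.10, 0.05, 0.20, 0.12, 0.04)))]]
  pc <- pc[, .(person_id, year, provider_type,
               amount_nominal = round(primary_amt * nf, 2))]
  setorder(pc, person_id, year, provider_type)

  income <- grid[, c(list(person_id = person_id, year = year,
                          personal_income_nominal = round(income_amt * nf, 2)),
                     lapply(.SD, function(x) round(x * nf, 2))),
                 .SDcols = TRANSFER_COLUMNS]
  setorder(income, person_id, year)

  bundle <- structure(list(
    civil = civil, psychiatric = psychiatric, drg_costs = drg,
    prescriptions = rx, primary_care = pc, income = income
  ), class = "register_bundle")

  ground_truth <- structure(list(
    persons = copy(civil),
    cases = dx,
    injections = inj[, .(person_id, disorder_name, year, inj_psych,
                         inj_somatic, inj_income, inj_transfer)],
    effects = copy(params$disorder_effects),
    params = params
  ), class = "ground_truth")

  list(bundle = bundle, ground_truth = ground_truth)
}

#' Expected estimands implied by a simulation's ground truth
#'
#' Direct enumeration of the injected excess amounts over realised case
#' person-years: for each disorder (and the any-disorder aggregate) the
#' expected per-case annual excess and nationwide annual excess per component,
#' and the expected years-since-diagnosis excess profile. Baseline costs
#' cancel between cases and matched controls in expectation, so these
#' enumerations are conditional expectations of the pipeline's excess
#' estimators given the realised cohort; the estimator should agree up to
#' sampling noise, which [aggregate_estimates()] quantifies via `mc_se`.
#'
#' When `matched_sets` is supplied the enumeration additionally subtracts the
#' injected amounts carried by the sampled controls (a control free of the
#' index disorder at the index date may be diagnosed later, or be a case of
#' another disorder), giving the exact conditional expectation of the
#' case-minus-control estimator. Without it the case-side enumeration ignores
#' this contamination and slightly overstates the expected excess.
#'
#' @param params the [sim_params()] used for the run.
#' @param ground_truth the matching `ground_truth`.
#' @param config a [study_config()].
#' @param matched_sets optionally, the `matched_sets` built from the bundle.
#' @return list of `data.table`s: `per_case` (disorder, component, expected),
#'   `nationwide` (disorder, component, expected), `profile` (disorder,
#'   offset_years, component, expected).
#' @export
expected_estimands <- function(params, ground_truth, config = study_config(),
                               matched_sets = NULL) {
  if (!is.null(matched_sets)) {
    return(expected_estimands_conditional(ground_truth, config, matched_sets))
  }
  gt <- ground_truth
  windows <- followup_windows(gt$persons, config)
  yrs <- study_years(config)

  case_tables <- list()
  inj_tables <- list()
  named <- unique(gt$effects$disorder_name)
  for (d in named) {
    cs <- gt$cases[disorder_name == d]
    case_tables[[d]] <- cs[, .(person_id, disorder_name = d, index_date = dx_date)]
    inj_tables[[d]] <- gt$injections[disorder_name == d]
  }
  any_cases <- gt$cases[, .(index_date = min(dx_date)), by = person_id]
  any_cases[, disorder_name := ANY_DISORDER]
  case_tables[[ANY_DISORDER]] <- any_cases[, .(person_id, disorder_name, index_date)]
  inj_any <- gt$injections[, .(inj_psych = sum(inj_psych),
                               inj_somatic = sum(inj_somatic),
                               inj_income = sum(inj_income),
                               inj_transfer = sum(inj_transfer)),
                           by = .(person_id, year)]
  inj_any[, disorder_name := ANY_DISORDER]
  inj_tables[[ANY_DISORDER]] <- inj_any

  duration <- study_duration_years(config)
  per_case <- list()
  nationwide <- list()
  profile <- list()
  for (d in names(case_tables)) {
    cs <- windows[case_tables[[d]], on = "person_id", nomatch = NULL]
    if (nrow(cs) == 0L) next
    pys <- cs[, .(year = yrs, py_post = year_fraction(pmax(index_date, start),
                                                      end, yrs)),
              by = .(person_id, index_date)][py_post > 0]
    total_py <- sum(pys$py_post)
    inj_d <- inj_tables[[d]][person_id %in% cs$person_id]
    tot <- inj_d[, .(psych_cost = sum(inj_psych), somatic_cost = sum(inj_somatic),
                     combined_healthcare_cost = sum(inj_psych + inj_somatic),
                     personal_income = -sum(inj_income),
                     transfers_total = sum(inj_transfer))]
    totl <- melt(tot, measure.vars = names(tot), variable.name = "component",
                 value.name = "total", variable.factor = FALSE)
    per_case[[d]] <- totl[, .(disorder_name = d, component,
                              expected = total / max(total_py, 1e-12))]
    nationwide[[d]] <- totl[, .(disorder_name = d, component,
                                expected = total / duration)]

    # profile restricted to cases identified in the profile window
    pc_cases <- cs[year(index_date) >= config$profile_case_window[1L]]
    if (nrow(pc_cases)) {
      inj_p <- inj_tables[[d]][person_id %in% pc_cases$person_id]
      inj_p <- pc_cases[, .(person_id, index_year = year(index_date))][
        inj_p, on = "person_id", nomatch = NULL]
      inj_p[, offset_years := year - index_year]
      py_p <- pys[person_id %in% pc_cases$person_id]
      py_p[, offset_years := year - year(index_date)]
      pyk <- py_p[, .(py = sum(py_post)), by = offset_years]
      num <- inj_p[, .(psych_cost = sum(inj_psych),
                       somatic_cost = sum(inj_somatic),
                       combined_healthcare_cost = sum(inj_psych + inj_somatic),
                       personal_income = -sum(inj_income),
                       transfers_total = sum(inj_transfer)),
                   by = offset_years]
      num <- melt(num, id.vars = "offset_years", variable.name = "component",
                  value.name = "total", variable.factor = FALSE)
      num <- pyk[num, on = "offset_years"]
      profile[[d]] <- num[py > 0, .(disorder_name = d, offset_years, component,
                                    expected = total / py)]
    }
  }
  list(per_case = rbindlist(per_case), nationwide = rbindlist(nationwide),
       profile = rbindlist(profile))
}

# Exact conditional expectation of the excess estimators given the realised
# cohort and sampled controls: enumerates injected amounts on both sides of
# every matched set (baseline costs have identical conditional means for a
# case and its controls, so they drop out of the expectation).
expected_estimands_conditional <- function(gt, config, ms) {
  windows <- followup_windows(gt$persons, config)
  yrs <- study_years(config)
  duration <- study_duration_years(config)

  injpy <- gt$injections[, .(psych = sum(inj_psych), somatic = sum(inj_somatic),
                             income = sum(inj_income),
                             transfer = sum(inj_transfer)),
                         by = .(person_id, year)]
  inj_cols <- c("psych", "somatic", "income", "transfer")

  sets <- ms$sets[!is.na(window_start)]
  cy <- sets[, .(year = yrs,
                 py = year_fraction(window_start, window_end, yrs),
                 py_post = year_fraction(pmax(index_date, window_start),
                                         window_end, yrs)),
             by = .(set_id, disorder_name, case_id, index_date)]
  cy <- cy[py_post > 0 & year >= year(index_date)]
  cy <- injpy[cy, on = c(person_id = "case_id", year = "year")]
  for (col in inj_cols) set(cy, which(is.na(cy[[col]])), col, 0)

  ctl <- ms$controls[sets[, .(set_id, index_year = year(index_date))],
                     on = "set_id", nomatch = NULL]
  ctl <- windows[ctl, on = c(person_id = "control_id"), nomatch = NULL]
  cty <- ctl[, .(year = yrs, py = year_fraction(start, end, yrs)),
             by = .(set_id, person_id, index_year)]
  cty <- cty[py > 0 & year >= index_year]
  cty <- injpy[cty, on = c("person_id", "year")]
  for (col in inj_cols) set(cty, which(is.na(cty[[col]])), col, 0)
  cagg <- cty[, .(ctrl_py = sum(py), c_psych = sum(psych),
                  c_somatic = sum(somatic), c_income = sum(income),
                  c_transfer = sum(transfer)), by = .(set_id, year)]

  d <- cagg[cy, on = c("set_id", "year")]
  d <- d[!is.na(ctrl_py) & ctrl_py > 0]
  d[, `:=`(
    e_psych = psych - py * c_psych / ctrl_py,
    e_somatic = somatic - py * c_somatic / ctrl_py,
    e_income = income - py * c_income / ctrl_py,
    e_transfer = transfer - py * c_transfer / ctrl_py
  )]
  tot <- d[, .(psych_cost = sum(e_psych), somatic_cost = sum(e_somatic),
               combined_healthcare_cost = sum(e_psych + e_somatic),
               personal_income = -sum(e_income),
               transfers_total = sum(e_transfer),
               py_post = sum(py_post)), by = disorder_name]
  comp_cols <- c("psych_cost", "somatic_cost", "combined_healthcare_cost",
                 "personal_income", "transfers_total")
  totl <- melt(tot, id.vars = c("disorder_name", "py_post"),
               measure.vars = comp_cols, variable.name = "component",
               value.name = "total", variable.factor = FALSE)
  per_case <- totl[, .(disorder_name, component,
                       expected = total / pmax(py_post, 1e-12))]
  nationwide <- totl[, .(disorder_name, component,
                         expected = total / duration)]

  dp <- d[index_date >= year_start(config$profile_case_window[1L])]
  dp[, offset_years := year - year(index_date)]
  pr <- dp[, .(psych_cost = sum(e_psych), somatic_cost = sum(e_somatic),
               combined_healthcare_cost = sum(e_psych + e_somatic),
               personal_income = -sum(e_income),
               transfers_total = sum(e_transfer),
               py_post = sum(py_post)), by = .(disorder_name, offset_years)]
  prl <- melt(pr, id.vars = c("disorder_name", "offset_years", "py_post"),
              measure.vars = comp_cols, variable.name = "component",
              value.name = "total", variable.factor = FALSE)
  profile <- prl[py_post > 0, .(disorder_name, offset_years, component,
                                expected = total / py_post)]
  setorder(profile, disorder_name, component, offset_years)
  list(per_case = per_case, nationwide = nationwide, profile = profile)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d persons, %d case records, %d injected case person-years\n",
              nrow(x$persons), nrow(x$cases), nrow(x$injections)))
  invisible(x)
}
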