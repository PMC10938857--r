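# Brute-force oracles: naive plain-R re-implementations used to cross-check
# the vectorised estimation and matching code on small inputs. Deliberately
# loop-based and independent of the data.table pipelines they verify.

# fraction of calendar year `yr` covered by [start, end), plain arithmetic
oracle_year_frac <- function(start, end, yr) {
  ys <- as.Date(sprintf("%d-01-01", yr))
  ye <- as.Date(sprintf("%d-01-01", yr + 1L))
  max(0, as.numeric(min(end, ye) - max(start, ys))) / as.numeric(ye - ys)
}

# eligibility scan for one case over a whole candidate pool
oracle_eligible <- function(case_id, index_date, persons, diagnoses,
                            definition, config) {
  persons <- as.data.frame(persons)
  diagnoses <- as.data.frame(diagnoses)
  case_row <- persons[persons$person_id == case_id, ]
  lo <- add_months_clamped(case_row$birth_date, -config$birthdate_tolerance_months)
  hi <- add_months_clamped(case_row$birth_date, config$birthdate_tolerance_months)
  ok <- character()
  for (i in seq_len(nrow(persons))) {
    p <- persons[i, ]
    if (p$person_id == case_id) next
    if (p$sex != case_row$sex) next
    if (p$birth_date < lo || p$birth_date > hi) next
    if (p$birth_date > index_date) next
    if (!is.na(p$immigration_date) && p$immigration_date > index_date) next
    if (!is.na(p$emigration_date) && p$emigration_date <= index_date) next
    if (!is.na(p$death_date) && p$death_date <= index_date) next
    ev <- diagnoses[diagnoses$person_id == p$person_id, ]
    if (nrow(ev)) {
      hit <- rep(FALSE, nrow(ev))
      for (pref in definition$icd10_codes[[1L]]) {
        hit <- hit | startsWith(ev$icd10_code, pref)
      }
      onset <- p$birth_date + round(definition$earliest_onset_age * 365.25)
      qual <- ev$event_date[hit & ev$event_date >= onset]
      if (length(qual) && min(qual) <= index_date) next
    }
    ok <- c(ok, p$person_id)
  }
  sort(ok)
}

# per-set-per-year excess for one component, looping over everything
oracle_set_year_excess <- function(ms, panels, component, config) {
  panels <- as.data.frame(panels)
  sets <- as.data.frame(ms$sets)
  controls <- as.data.frame(ms$controls)
  rows <- list()
  for (i in seq_len(nrow(sets))) {
    s <- sets[i, ]
    if (is.na(s$window_start)) next
    for (yr in study_years(config)) {
      if (yr < as.integer(format(s$index_date, "%Y"))) next
      py_post <- oracle_year_frac(max(s$index_date, s$window_start),
                                  s$window_end, yr)
      if (py_post <= 0) next
      crow <- panels[panels$person_id == s$case_id & panels$year == yr, ]
      if (nrow(crow) == 0L) next
      ids <- controls$control_id[controls$set_id == s$set_id]
      ctl <- panels[panels$person_id %in% ids & panels$year == yr, ]
      if (nrow(ctl) == 0L || sum(ctl$py) <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = s$set_id, disorder_name = s$disorder_name, year = yr,
        case_sex = s$case_sex,
        age = {
          bl <- as.POSIXlt(s$case_birth)
          yr - (bl$year + 1900L) -
            1L + as.integer((bl$mon + 1L) < 7L |
                              ((bl$mon + 1L) == 7L & bl$mday <= 1L))
        },
        py_post = py_post,
        abs_value = crow[[component]],
        exc_value = crow[[component]] -
          crow$py * sum(ctl[[component]]) / sum(ctl$py))
    }
  }
  do.call(rbind, rows)
}

# full oracle recomputation of the overall/sex/age-band estimates for one
# component (person-year weighting)
oracle_estimates <- function(ms, panels, denominators, component, config) {
  sy <- oracle_set_year_excess(ms, panels, component, config)
  duration <- sum(sapply(study_years(config), function(yr) {
    oracle_year_frac(config$followup_start, config$followup_end, yr)
  }))
  sy$band <- regcost:::age_band(pmax(0L, as.integer(sy$age)))
  den <- as.data.frame(denominators)
  out <- list()
  emit <- function(sub, stratum_type, stratum, denom) {
    if (nrow(sub) == 0L) return()
    out[[length(out) + 1L]] <<- data.frame(
      disorder_name = sub$disorder_name[1L], stratum_type = stratum_type,
      stratum = stratum,
      nationwide_abs = sum(sub$abs_value) / duration,
      nationwide_exc = sum(sub$exc_value) / duration,
      per_case_abs = sum(sub$abs_value) / sum(sub$py_post),
      per_case_exc = sum(sub$exc_value) / sum(sub$py_post),
      per_capita_exc = sum(sub$exc_value) / duration / denom,
      n_py = sum(sub$py_post))
  }
  for (d in unique(sy$disorder_name)) {
    sd_ <- sy[sy$disorder_name == d, ]
    emit(sd_, "overall", "overall", sum(den$count))
    for (sx in unique(sd_$case_sex)) {
      emit(sd_[sd_$case_sex == sx, ], "sex", sx,
           sum(den$count[den$sex == sx]))
    }
    for (b in unique(sd_$band)) {
      emit(sd_[sd_$band == b, ], "age_band", b,
           sum(den$count[den$age_band_lab == b]))
    }
  }
  do.call(rbind, out)
}
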