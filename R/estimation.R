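# Estimation of absolute and excess estimands from matched sets and annual
# cost panels.
#
# Within a matched set and calendar year, the excess for a component is
#   case value - case person-time x (sum of control values / sum of control
#   person-time),
# i.e. the case's annual amount minus the control group's person-year-weighted
# rate scaled to the case's person-time. Under identical cost processes this
# is exactly zero in expectation regardless of censoring patterns. Sets whose
# controls have no person-time in a year are skipped for that year and
# counted in the diagnostics attribute.

# set-year level case values and excess differences, one column pair per
# component; the engine behind all estimands
set_year_differences <- function(ms, panels, config = study_config()) {
  sets <- ms$sets[!is.na(window_start)]
  if (nrow(sets) == 0L) {
    abort("no matched sets with follow-up windows", class = "regcost_estimation_error")
  }
  panels <- as.data.table(panels)

  cy <- panels[sets, on = c(person_id = "case_id"),
               allow.cartesian = TRUE, nomatch = NULL]
  setnames(cy, "person_id", "case_id")
  cy <- cy[year >= year(index_date)]
  cy[, py_post := year_fraction(pmax(index_date, window_start), window_end, year)]
  cy <- cy[py_post > 0]

  ctl <- ms$controls[sets[, .(set_id, index_year = year(index_date))],
                     on = "set_id", nomatch = NULL]
  cty <- panels[ctl, on = c(person_id = "control_id"),
                allow.cartesian = TRUE, nomatch = NULL]
  cty <- cty[year >= index_year]
  cagg <- cty[, c(list(ctrl_py = sum(py)),
                  lapply(.SD, sum)),
              by = .(set_id, year), .SDcols = COST_COMPONENTS]
  setnames(cagg, COST_COMPONENTS, paste0("ctrl_", COST_COMPONENTS))

  d <- cagg[cy, on = c("set_id", "year")]
  skipped <- d[is.na(ctrl_py) | ctrl_py <= 0,
               .(set_id, year, disorder_name)]
  d <- d[!is.na(ctrl_py) & ctrl_py > 0]
  for (comp in COST_COMPONENTS) {
    set(d, j = paste0("d_", comp),
        value = d[[comp]] - d$py * d[[paste0("ctrl_", comp)]] / d$ctrl_py)
    set(d, j = paste0("ctrl_", comp), value = NULL)
  }
  setattr(d, "skipped_set_years", skipped)
  d
}

check_component <- function(component) {
  if (!component %in% COST_COMPONENTS) {
    abort(paste0("unknown component '", component, "'; expected one of: ",
                 paste(COST_COMPONENTS, collapse = ", ")),
          class = "regcost_component_error")
  }
  component
}

#' Nationwide excess for one component and calendar year
#'
#' Sum over matched sets with case person-time in the year of the case value
#' minus the person-year-weighted control mean, in 2017 Euro.
#'
#' @param ms a `matched_sets` object.
#' @param panels cost panels from [build_cost_panels()].
#' @param component one of the component names in `regcost:::COST_COMPONENTS`.
#' @param year a calendar year covered by the panels.
#' @param config a [study_config()].
#' @return named numeric vector, one value per disorder present in `ms`; the
#'   `skipped_set_years` attribute lists set-years without surviving controls.
#' @export
excess_by_year <- function(ms, panels, component, year,
                           config = study_config()) {
  check_component(component)
  d <- set_year_differences(ms, panels, config)
  yr <- as.integer(year)
  out <- d[year == yr,
           .(value = sum(.SD[[1L]])), by = disorder_name,
           .SDcols = paste0("d_", component)]
  res <- setNames(out$value, out$disorder_name)
  skipped <- attr(d, "skipped_set_years")
  attr(res, "skipped_set_years") <- skipped[year == yr]
  res
}

# melt set-year wide table to long (one row per set-year-component)
melt_set_year <- function(d, extra = character()) {
  id_cols <- c("set_id", "disorder_name", "case_sex", "case_birth", "year",
               "py", "py_post", extra)
  long <- melt(
    d[, c(id_cols, COST_COMPONENTS, paste0("d_", COST_COMPONENTS)), with = FALSE],
    id.vars = id_cols,
    measure.vars = list(COST_COMPONENTS, paste0("d_", COST_COMPONENTS)),
    value.name = c("abs_value", "exc_value"),
    variable.name = "component", variable.factor = FALSE
  )
  long[, component := COST_COMPONENTS[as.integer(component)]]
  long
}

denominator_for <- function(denominators, stratum_type) {
  den <- as.data.table(denominators)
  if (stratum_type == "overall") {
    den[, .(stratum = "overall", count = sum(count))]
  } else if (stratum_type == "sex") {
    den[, .(count = sum(count)), by = .(stratum = sex)]
  } else {
    den[, .(count = sum(count)), by = .(stratum = age_band_lab)]
  }
}

#' Aggregate matched-cohort estimands
#'
#' Computes, for every disorder, cost component and stratum (overall, by sex,
#' by 5-year attained-age band), the three measures: nationwide annual
#' (person-year-weighted average yearly total over the study window), average
#' annual per case (total over follow-up divided by case person-years counted
#' from the index date) and annual per capita (nationwide divided by the
#' stratum's population denominator), each for absolute cost (cases' own
#' costs) and excess cost (case minus matched-control difference; negative
#' values for income mean cases earn less than their controls). `mc_se` is a
#' between-set sampling standard error for the excess measures (ratio-
#' estimator form for per-case values).
#'
#' @param ms a `matched_sets` object.
#' @param panels cost panels from [build_cost_panels()].
#' @param denominators population denominators: a `data.table` with columns
#'   `sex`, `age_band_lab`, `count` (see [compute_population_denominators()]),
#'   or `NULL` to skip per-capita measures.
#' @param config a [study_config()].
#' @return a tidy `data.table`: `disorder_name`, `measure`, `cost_kind`,
#'   `component`, `stratum_type`, `stratum`, `value`, `n_case_person_years`,
#'   `n_sets`, `mc_se`; diagnostics (skipped set-years, strata dropped for
#'   missing denominators) in attributes.
#' @export
aggregate_estimates <- function(ms, panels, denominators = NULL,
                                config = study_config()) {
  d <- set_year_differences(ms, panels, config)
  duration <- study_duration_years(config)
  d[, band := age_band(attained_age(case_birth, year))]
  long <- melt_set_year(d, extra = "band")

  out <- list()
  dropped <- list()
  for (st in c("overall", "sex", "age_band")) {
    x <- copy(long)
    if (st == "overall") x[, stratum := "overall"]
    if (st == "sex") x[, stratum := case_sex]
    if (st == "age_band") x[, stratum := band]

    per_set <- x[, .(T = sum(exc_value), A = sum(abs_value),
                     P = sum(py_post)),
                 by = .(disorder_name, component, stratum, set_id)]
    grp <- per_set[, {
      n <- .N
      sum_T <- sum(T); sum_A <- sum(A); sum_P <- sum(P)
      R <- if (sum_P > 0) sum_T / sum_P else NA_real_
      infl <- if (n > 1L) n / (n - 1) else NA_real_
      se_total <- sqrt(infl * sum((T - mean(T))^2))
      se_ratio <- if (sum_P > 0) sqrt(infl * sum((T - R * P)^2)) / sum_P
                  else NA_real_
      per_case_abs <- if (config$per_case_weighting == "persons") {
        mean((A / pmax(P, 1e-12))[P > 0])
      } else sum_A / sum_P
      per_case_exc <- if (config$per_case_weighting == "persons") {
        mean((T / pmax(P, 1e-12))[P > 0])
      } else R
      .(n_sets = n, sum_T = sum_T, sum_A = sum_A, sum_P = sum_P,
        per_case_abs = per_case_abs, per_case_exc = per_case_exc,
        se_total = se_total, se_ratio = se_ratio)
    }, by = .(disorder_name, component, stratum)]

    rows <- rbind(
      grp[, .(disorder_name, component, stratum,
              measure = "nationwide_annual", cost_kind = "absolute",
              value = sum_A / duration, n_case_person_years = sum_P,
              n_sets, mc_se = NA_real_)],
      grp[, .(disorder_name, component, stratum,
              measure = "nationwide_annual", cost_kind = "excess",
              value = sum_T / duration, n_case_person_years = sum_P,
              n_sets, mc_se = se_total / duration)],
      grp[sum_P > 0, .(disorder_name, component, stratum,
                       measure = "per_case_annual", cost_kind = "absolute",
                       value = per_case_abs, n_case_person_years = sum_P,
                       n_sets, mc_se = NA_real_)],
      grp[sum_P > 0, .(disorder_name, component, stratum,
                       measure = "per_case_annual", cost_kind = "excess",
                       value = per_case_exc, n_case_person_years = sum_P,
                       n_sets, mc_se = se_ratio)]
    )

    if (!is.null(denominators)) {
      den <- denominator_for(denominators, st)
      nat <- rows[measure == "nationwide_annual"]
      miss <- setdiff(unique(nat$stratum), den[count > 0]$stratum)
      if (length(miss)) {
        dropped[[st]] <- data.table(stratum_type = st, stratum = miss)
      }
      percap <- den[count > 0][nat, on = "stratum", nomatch = NULL]
      percap <- percap[, .(disorder_name, component, stratum,
                           measure = "per_capita_annual", cost_kind,
                           value = value / count,
                           n_case_person_years, n_sets,
                           mc_se = mc_se / count)]
      rows <- rbind(rows, percap)
    }
    rows[, stratum_type := st]
    out[[st]] <- rows
  }
  res <- rbindlist(out, fill = TRUE)
  if (length(dropped)) {
    setattr(res, "dropped_percapita_strata", rbindlist(dropped))
  }
  setcolorder(res, c("disorder_name", "measure", "cost_kind", "component",
                     "stratum_type", "stratum", "value",
                     "n_case_person_years", "n_sets", "mc_se"))
  setorder(res, disorder_name, measure, cost_kind, component, stratum_type,
           stratum)
  setattr(res, "skipped_set_years", attr(d, "skipped_set_years"))
  res[]
}

#' Excess-cost profile by years since diagnosis
#'
#' Person-year-weighted excess per component at each whole-year offset since
#' the diagnosis year (offset k = calendar year minus index year, 0..13).
#' Only cases identified within the profile case window (2004-2017 by
#' default) contribute, since cost data must exist from the index date on.
#'
#' @inheritParams aggregate_estimates
#' @param max_offset largest offset reported.
#' @return `data.table`: `disorder_name`, `offset_years`, `component`,
#'   `value`, `n_case_person_years`, `n_sets`, `mc_se`.
#' @export
years_since_diagnosis_profile <- function(ms, panels, config = study_config(),
                                          max_offset = 13L) {
  lo <- year_start(config$profile_case_window[1L])
  hi <- year_start(config$profile_case_window[2L] + 1L)
  sub <- list(
    sets = ms$sets[index_date >= lo & index_date < hi],
    controls = ms$controls
  )
  class(sub) <- "matched_sets"
  if (nrow(sub$sets) == 0L) {
    abort("no cases identified within the profile case window",
          class = "regcost_estimation_error")
  }
  d <- set_year_differences(sub, panels, config)
  d[, offset_years := year - year(index_date)]
  d <- d[offset_years >= 0L & offset_years <= max_offset]
  long <- melt_set_year(d, extra = "offset_years")
  per_set <- long[, .(T = sum(exc_value), P = sum(py_post)),
                  by = .(disorder_name, component, offset_years, set_id)]
  res <- per_set[, {
    n <- .N
    sum_T <- sum(T); sum_P <- sum(P)
    R <- if (sum_P > 0) sum_T / sum_P else NA_real_
    infl <- if (n > 1L) n / (n - 1) else NA_real_
    .(value = R, n_case_person_years = sum_P, n_sets = n,
      mc_se = if (sum_P > 0) sqrt(infl * sum((T - R * P)^2)) / sum_P
              else NA_real_)
  }, by = .(disorder_name, component, offset_years)]
  setorder(res, disorder_name, component, offset_years)
  res[]
}
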