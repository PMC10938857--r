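#' Study configuration
#'
#' Defaults encode the study design: persons are followed from 1 January 2004,
#' birth or immigration (whichever is last) until death, the 95th birthday,
#' emigration or 23 April 2017 (whichever is first); cases are first qualifying
#' diagnoses registered 1995-2017; each case receives up to 10 controls of the
#' same sex, birthdate within two calendar months, free of the index disorder
#' at the index date.
#'
#' @param followup_start,followup_end follow-up window bounds (`end` exclusive).
#' @param case_window integer `c(first, last)` calendar years in which index
#'   diagnoses qualify.
#' @param profile_case_window as `case_window`, but for the years-since-
#'   diagnosis analysis, where cost data must exist from the index date on.
#' @param censor_age age in years at which follow-up is censored.
#' @param controls_per_case controls drawn per case.
#' @param birthdate_tolerance_months matching tolerance, calendar months.
#' @param control_history `"at_index"` (controls must be index-disorder free on
#'   the index date; later diagnoses do not retract them) or `"ever"`
#'   (index-disorder free for their whole recorded history).
#' @param per_case_weighting `"person_years"` (per-case annual estimates divide
#'   by case person-years) or `"persons"` (simple mean over cases of each
#'   case's annual average).
#' @param seed integer seed driving control sampling.
#' @return a list with class `study_config`.
#' @export
study_config <- function(followup_start = as.Date("2004-01-01"),
                         followup_end = as.Date("2017-04-23"),
                         case_window = c(1995L, 2017L),
                         profile_case_window = c(2004L, 2017L),
                         censor_age = 95L,
                         controls_per_case = 10L,
                         birthdate_tolerance_months = 2L,
                         control_history = c("at_index", "ever"),
                         per_case_weighting = c("person_years", "persons"),
                         seed = 1L) {
  followup_start <- as.Date(followup_start)
  followup_end <- as.Date(followup_end)
  stopifnot(
    followup_start < followup_end,
    length(case_window) == 2L, case_window[1L] <= case_window[2L],
    case_window[2L] >= as.integer(format(followup_end, "%Y")),
    censor_age > 0, controls_per_case >= 1L, birthdate_tolerance_months >= 0L
  )
  structure(list(
    followup_start = followup_start,
    followup_end = followup_end,
    case_window = as.integer(case_window),
    profile_case_window = as.integer(profile_case_window),
    censor_age = as.integer(censor_age),
    controls_per_case = as.integer(controls_per_case),
    birthdate_tolerance_months = as.integer(birthdate_tolerance_months),
    control_history = match.arg(control_history),
    per_case_weighting = match.arg(per_case_weighting),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Calendar years of cost observation
#'
#' @param config a [study_config()].
#' @return integer vector of the calendar years intersecting the follow-up
#'   window (14 years, 2004-2017, under the defaults).
#' @export
study_years <- function(config = study_config()) {
  seq(as.integer(format(config$followup_start, "%Y")),
      as.integer(format(config$followup_end - 1L, "%Y")))
}

# Fraction of each study year covered by the follow-up window; the final year
# is partial (112/365 under the defaults).
study_year_coverage <- function(config = study_config()) {
  yrs <- study_years(config)
  setNames(year_fraction(config$followup_start, config$followup_end, yrs), yrs)
}

# Total length of the study window in years; the denominator behind
# "average annual" estimands.
study_duration_years <- function(config = study_config()) {
  sum(study_year_coverage(config))
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  follow-up          [%s, %s)\n", x$followup_start, x$followup_end))
  cat(sprintf("  case window        %d-%d (profile: %d-%d)\n",
              x$case_window[1L], x$case_window[2L],
              x$profile_case_window[1L], x$profile_case_window[2L]))
  cat(sprintf("  censoring age      %d\n", x$censor_age))
  cat(sprintf("  controls per case  %d (sex, birthdate +/- %d months, %s)\n",
              x$controls_per_case, x$birthdate_tolerance_months, x$control_history))
  invisible(x)
}
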