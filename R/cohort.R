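# Cohort construction: censored follow-up windows, case identification per
# disorder, and incidence-density matched controls.

#' Follow-up windows
#'
#' `followup_windows()` computes, for every person in a civil register table,
#' the half-open interval `[start, end)` with
#' `start = max(followup_start, birth, immigration)` and
#' `end = min(death, censor-age birthday, emigration, followup_end)`.
#' Persons whose interval is empty (`start >= end`) are dropped.
#' `followup_window()` is the single-person form and returns `NULL` for an
#' empty interval.
#'
#' @param persons a civil register table.
#' @param person a one-row civil register table (or list with the same fields).
#' @param config a [study_config()].
#' @return a `data.table` with columns `person_id`, `start`, `end`
#'   (`followup_window()`: one row or `NULL`).
#' @export
followup_windows <- function(persons, config = study_config()) {
  persons <- as.data.table(persons)
  na_date <- as.Date(NA)
  imm <- fifelse(is.na(persons$immigration_date), persons$birth_date,
                 persons$immigration_date)
  start <- pmax(config$followup_start, persons$birth_date, imm)
  cap <- add_years_clamped(persons$birth_date, config$censor_age)
  end <- pmin(
    fifelse(is.na(persons$death_date), config$followup_end,
            persons$death_date),
    fifelse(is.na(persons$emigration_date), config$followup_end,
            persons$emigration_date),
    cap,
    config$followup_end
  )
  out <- data.table(person_id = persons$person_id, start = start, end = end)
  out[start < end]
}

#' @rdname followup_windows
#' @export
followup_window <- function(person, config = study_config()) {
  w <- followup_windows(as.data.table(as.list(person)), config)
  if (nrow(w) == 0L) return(NULL)
  w
}

#' First qualifying diagnosis per person for one disorder
#'
#' A diagnosis event qualifies when its ICD-10 code starts with one of the
#' definition's prefixes and the person's age at the event is at least the
#' definition's assumed earliest onset age. Used both for case identification
#' and for the index-disorder-free eligibility check on candidate controls.
#'
#' @param diagnoses a psychiatric register table.
#' @param persons a civil register table (for birth dates).
#' @param definition one catalogue row (see [load_disorder_catalogue()]).
#' @return `data.table` with columns `person_id`, `first_date`.
#' @export
first_qualifying_diagnosis <- function(diagnoses, persons, definition) {
  diagnoses <- as.data.table(diagnoses)
  hits <- diagnoses[icd_prefix_match(icd10_code, definition$icd10_codes[[1L]])]
  if (nrow(hits) == 0L) {
    return(data.table(person_id = character(), first_date = as.Date(character())))
  }
  hits <- hits[as.data.table(persons)[, .(person_id, birth_date)],
               on = "person_id", nomatch = NULL]
  onset <- add_years_clamped(hits$birth_date,
                             as.integer(ceiling(definition$earliest_onset_age)))
  # fractional onset ages are carried exactly via days
  if (definition$earliest_onset_age %% 1 != 0) {
    onset <- hits$birth_date +
      round(definition$earliest_onset_age * 365.25)
  }
  hits <- hits[hits$event_date >= onset]
  hits[, .(first_date = min(event_date)), by = person_id]
}

#' Identify cases for one disorder
#'
#' A person is a case when they have at least one qualifying diagnosis event
#' (code match, age at event at or above the assumed earliest onset age) dated
#' within the case window; the index date is the earliest such event. A person
#' can be a case for several disorders, once per disorder.
#'
#' @inheritParams first_qualifying_diagnosis
#' @param config a [study_config()].
#' @param case_window optional integer `c(first, last)` overriding
#'   `config$case_window` (the years-since-diagnosis analysis restricts
#'   identification to 2004-2017).
#' @return `data.table` with columns `person_id`, `disorder_name`,
#'   `index_date`, sorted by `(index_date, person_id)`.
#' @export
identify_cases <- function(diagnoses, persons, definition,
                           config = study_config(), case_window = NULL) {
  if (is.null(case_window)) case_window <- config$case_window
  diagnoses <- as.data.table(diagnoses)
  in_window <- diagnoses[
    year(event_date) >= case_window[1L] & year(event_date) <= case_window[2L]]
  first <- first_qualifying_diagnosis(in_window, persons, definition)
  out <- first[, .(person_id, disorder_name = definition$disorder_name,
                   index_date = first_date)]
  setorder(out, index_date, person_id)
  out[]
}

# Deterministic per-case RNG substream seed: mixes the study seed with the
# disorder index and the case's rank in canonical (index_date, person_id)
# order, so matching does not depend on input row order.
mix_seed <- function(seed, disorder_idx, case_rank) {
  as.integer((as.numeric(seed) + 1000003 * disorder_idx +
                2654435761 * case_rank) %% 2147483647)
}

#' Match controls to cases of one disorder
#'
#' For each case, draws a uniformly random sample (seeded, reproducible) of up
#' to `controls_per_case` candidates who share the case's sex, have a birthdate
#' within the calendar-month tolerance, are alive and resident on the index
#' date, and have no qualifying index-disorder diagnosis on or before the
#' index date. Sets that cannot be filled are returned with fewer controls and
#' reported via a warning and the `deficient_sets` attribute.
#'
#' @param cases output of [identify_cases()] (one disorder; one or many rows).
#' @param persons a civil register table: the candidate pool.
#' @param diagnoses a psychiatric register table (for the disorder-free rule).
#' @param definition the catalogue row of the index disorder.
#' @param config a [study_config()].
#' @param disorder_idx integer used to separate RNG substreams between
#'   disorders when matching a whole catalogue.
#' @return a `matched_sets` object: list with `$sets` (one row per case:
#'   `set_id`, `disorder_name`, `case_id`, `case_sex`, `case_birth`,
#'   `index_date`, `window_start`, `window_end`, `n_controls`) and `$controls`
#'   (`set_id`, `control_id`).
#' @export
match_controls <- function(cases, persons, diagnoses, definition,
                           config = study_config(), disorder_idx = 1L) {
  cases <- as.data.table(cases)
  persons <- as.data.table(persons)
  setorder(cases, index_date, person_id)
  cases[, case_rank := seq_len(.N)]

  tol <- config$birthdate_tolerance_months
  pool <- persons[, .(person_id, sex, birth_date, immigration_date,
                      emigration_date, death_date)]
  pidx <- match(cases$person_id, persons$person_id)
  key <- data.table(case_id = cases$person_id, case_rank = cases$case_rank,
                    index_date = cases$index_date,
                    sex = persons$sex[pidx],
                    case_birth = persons$birth_date[pidx])
  key[, `:=`(lo = add_months_clamped(case_birth, -tol),
             hi = add_months_clamped(case_birth, tol))]

  pairs <- pool[key, on = .(sex, birth_date >= lo, birth_date <= hi),
                allow.cartesian = TRUE,
                .(case_rank, case_id, index_date,
                  control_id = x.person_id, control_birth = x.birth_date,
                  immigration_date = x.immigration_date,
                  emigration_date = x.emigration_date,
                  death_date = x.death_date)]
  pairs <- pairs[control_id != case_id]
  # alive and resident on the index date
  pairs <- pairs[
    control_birth <= index_date &
      (is.na(immigration_date) | immigration_date <= index_date) &
      (is.na(emigration_date) | emigration_date > index_date) &
      (is.na(death_date) | death_date > index_date)]
  # free of the index disorder at the index date (or ever)
  first_dx <- first_qualifying_diagnosis(diagnoses, persons, definition)
  pairs <- first_dx[pairs, on = c(person_id = "control_id")]
  setnames(pairs, "person_id", "control_id")
  if (config$control_history == "ever") {
    pairs <- pairs[is.na(first_date)]
  } else {
    pairs <- pairs[is.na(first_date) | first_date > index_date]
  }

  k <- config$controls_per_case
  base_seed <- config$seed
  setorder(pairs, case_rank, control_id)
  picked <- if (nrow(pairs)) {
    pairs[, {
      n <- .N
      idx <- if (n <= k) seq_len(n) else {
        set.seed(mix_seed(base_seed, disorder_idx, case_rank[1L]))
        sample.int(n, k)
      }
      .(control_id = control_id[idx])
    }, by = case_rank]
  } else {
    data.table(case_rank = integer(), control_id = character())
  }

  windows <- followup_windows(persons, config)
  sets <- cases[, .(case_rank, disorder_name, case_id = person_id, index_date)]
  sidx <- match(sets$case_id, persons$person_id)
  sets[, `:=`(case_sex = persons$sex[sidx],
              case_birth = persons$birth_date[sidx])]
  sets <- windows[sets, on = c(person_id = "case_id")]
  setnames(sets, c("person_id", "start", "end"),
           c("case_id", "window_start", "window_end"))
  nctl <- picked[, .N, by = case_rank]
  sets[, n_controls := 0L]
  sets[nctl, n_controls := i.N, on = "case_rank"]
  sets[, set_id := paste0(definition$disorder_name, "#", case_rank)]
  controls <- picked[sets[, .(case_rank, set_id)], on = "case_rank",
                     .(set_id, control_id)][!is.na(control_id)]
  deficient <- sets[n_controls < k,
                    .(set_id, case_id, index_date, n_controls)]
  if (nrow(deficient)) {
    warn(sprintf(
      "%d of %d matched sets for '%s' have fewer than %d controls",
      nrow(deficient), nrow(sets), definition$disorder_name, k))
  }
  setorder(sets, case_rank)
  sets[, case_rank := NULL]
  setcolorder(sets, c("set_id", "disorder_name", "case_id", "case_sex",
                      "case_birth", "index_date", "window_start", "window_end",
                      "n_controls"))
  structure(list(sets = sets[], controls = controls[]),
            class = "matched_sets",
            deficient_sets = deficient)
}

#' Build the matched cohort for a whole catalogue
#'
#' Runs [identify_cases()] and [match_controls()] for every definition in the
#' catalogue and binds the results.
#'
#' @param persons,diagnoses civil and psychiatric register tables.
#' @param catalogue a disorder catalogue.
#' @param config a [study_config()].
#' @param case_window optional override of the identification window.
#' @return a `matched_sets` object covering all disorders; the per-disorder
#'   case counts are in the `case_counts` attribute.
#' @export
build_matched_cohort <- function(persons, diagnoses, catalogue,
                                 config = study_config(), case_window = NULL) {
  pieces <- lapply(seq_len(nrow(catalogue)), function(i) {
    def <- catalogue[i]
    cases <- identify_cases(diagnoses, persons, def, config, case_window)
    if (nrow(cases) == 0L) return(NULL)
    withCallingHandlers(
      match_controls(cases, persons, diagnoses, def, config, disorder_idx = i),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  sets <- rbindlist(lapply(pieces, `[[`, "sets"))
  controls <- rbindlist(lapply(pieces, `[[`, "controls"))
  deficient <- rbindlist(lapply(pieces, attr, "deficient_sets"))
  if (nrow(deficient)) {
    warn(sprintf("%d matched sets are deficient (fewer than %d controls)",
                 nrow(deficient), config$controls_per_case))
  }
  structure(list(sets = sets, controls = controls),
            class = "matched_sets",
            deficient_sets = deficient,
            case_counts = sets[, .(n_cases = .N), by = disorder_name])
}

#' Check every matched-set invariant
#'
#' Exhaustively re-checks, for every set: the case is not among its controls;
#' controls share the case's sex; control birthdates are within the
#' calendar-month tolerance; controls are alive and resident on the index
#' date; no control has a qualifying index-disorder diagnosis on or before the
#' index date; and the set has at most `controls_per_case` controls.
#'
#' @param ms a `matched_sets` object.
#' @param persons,diagnoses the registers the sets were built from.
#' @param catalogue the disorder catalogue.
#' @param config a [study_config()].
#' @return `data.table` with one row per set and logical columns per rule,
#'   plus `all_ok`.
#' @export
check_matched_sets <- function(ms, persons, diagnoses, catalogue,
                               config = study_config()) {
  persons <- as.data.table(persons)
  long <- ms$controls[ms$sets, on = "set_id",
                      .(set_id, disorder_name, case_id, case_sex, case_birth,
                        index_date, control_id)]
  long <- long[!is.na(control_id)]
  cidx <- match(long$control_id, persons$person_id)
  long[, `:=`(
    ctl_sex = persons$sex[cidx],
    ctl_birth = persons$birth_date[cidx],
    ctl_imm = persons$immigration_date[cidx],
    ctl_emi = persons$emigration_date[cidx],
    ctl_death = persons$death_date[cidx]
  )]
  tol <- config$birthdate_tolerance_months
  long[, `:=`(
    ok_not_self = control_id != case_id,
    ok_sex = ctl_sex == case_sex,
    ok_birth = ctl_birth >= add_months_clamped(case_birth, -tol) &
      ctl_birth <= add_months_clamped(case_birth, tol),
    ok_alive = (is.na(ctl_death) | ctl_death > index_date) &
      ctl_birth <= index_date,
    ok_resident = (is.na(ctl_imm) | ctl_imm <= index_date) &
      (is.na(ctl_emi) | ctl_emi > index_date)
  )]
  long[, ok_disorder_free := TRUE]
  for (i in seq_len(nrow(catalogue))) {
    def <- catalogue[i]
    sub <- long$disorder_name == def$disorder_name
    if (!any(sub)) next
    fdx <- first_qualifying_diagnosis(diagnoses, persons, def)
    fd <- fdx[match(long$control_id[sub], fdx$person_id), first_date]
    long$ok_disorder_free[sub] <- is.na(fd) | fd > long$index_date[sub]
  }
  per_set <- long[, .(
    ok_not_self = all(ok_not_self), ok_sex = all(ok_sex),
    ok_birth = all(ok_birth), ok_alive = all(ok_alive),
    ok_resident = all(ok_resident), ok_disorder_free = all(ok_disorder_free),
    ok_no_dup = !anyDuplicated(control_id)
  ), by = set_id]
  res <- per_set[ms$sets[, .(set_id, n_controls)], on = "set_id"]
  for (col in grep("^ok_", names(res), value = TRUE)) {
    set(res, which(is.na(res[[col]])), col, TRUE)  # zero-control sets
  }
  res[, ok_size := n_controls <= config$controls_per_case]
  res[, all_ok := ok_not_self & ok_sex & ok_birth & ok_alive & ok_resident &
        ok_disorder_free & ok_no_dup & ok_size]
  res[]
}

#' @export
print.matched_sets <- function(x, ...) {
  cat("<matched_sets>\n")
  cat(sprintf("  %d sets across %d disorders, %d control assignments\n",
              nrow(x$sets), length(unique(x$sets$disorder_name)),
              nrow(x$controls)))
  def <- attr(x, "deficient_sets")
  if (!is.null(def) && nrow(def)) {
    cat(sprintf("  %d deficient sets\n", nrow(def)))
  }
  invisible(x)
}

#' Write matched sets as a delimited table
#'
#' One row per set: case id, disorder, index date, and the control ids joined
#' with `";"`.
#'
#' @param ms a `matched_sets` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matched_sets <- function(ms, path) {
  ctl <- ms$controls[, .(control_ids = paste(sort(control_id), collapse = ";")),
                     by = set_id]
  out <- ctl[ms$sets, on = "set_id",
             .(set_id, disorder_name, case_id, index_date, n_controls,
               control_ids = fifelse(is.na(control_ids), "", control_ids))]
  fwrite(out, path, sep = ",", quote = FALSE)
  invisible(path)
}
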