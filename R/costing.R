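# Cost assembly: nominal register amounts -> per-person per-calendar-year
# panels in inflation-adjusted 2017 Euro.

#' Deflator table
#'
#' Pairs a GDP-deflator index series (one value per study year, used to
#' restate nominal amounts at 2017 price level) with the average 2017 exchange
#' rate in local-currency units per Euro.
#'
#' @param deflator named numeric vector, names are years; strictly positive.
#' @param fx_rate_2017 local currency per Euro, strictly positive.
#' @return a list with class `deflator_table`.
#' @export
deflator_table <- function(deflator, fx_rate_2017) {
  years <- as.integer(names(deflator))
  stopifnot(!anyNA(years), all(deflator > 0), fx_rate_2017 > 0)
  structure(list(deflator = setNames(as.numeric(deflator), years),
                 fx_rate_2017 = as.numeric(fx_rate_2017)),
            class = "deflator_table")
}

#' Bundled deflator series
#'
#' A Denmark-like GDP-deflator index for 2004-2017 (2017 = 102.0) and the
#' 2017 average Danish krone/Euro exchange rate (7.4386). Synthetic default
#' values for use with simulated registers; analyses of real extracts should
#' supply the official series.
#'
#' @return a [deflator_table()].
#' @export
default_deflator_table <- function() {
  deflator_table(
    c("2004" = 82.0, "2005" = 84.3, "2006" = 86.2, "2007" = 88.3,
      "2008" = 91.5, "2009" = 92.2, "2010" = 95.0, "2011" = 95.6,
      "2012" = 98.0, "2013" = 99.0, "2014" = 100.1, "2015" = 100.9,
      "2016" = 101.0, "2017" = 102.0),
    fx_rate_2017 = 7.4386
  )
}

#' Convert nominal amounts to 2017 Euro
#'
#' `amount * deflator(2017) / deflator(year) / fx_rate_2017`: inflation
#' adjustment from the year the cost occurred to 2017, then conversion at the
#' 2017 average exchange rate. Linear in `amount`; the identity (up to the
#' currency conversion) for `year = 2017`.
#'
#' @param amount_nominal numeric vector of nominal local-currency amounts.
#' @param year integer vector of the years the amounts occurred (recycled).
#' @param deflator a [deflator_table()].
#' @return numeric vector in 2017 Euro.
#' @export
to_eur2017 <- function(amount_nominal, year, deflator = default_deflator_table()) {
  idx <- match(as.integer(year), as.integer(names(deflator$deflator)))
  if (anyNA(idx)) {
    abort(paste0("no deflator for year ",
                 paste(unique(year[is.na(idx)]), collapse = ", ")),
          class = "regcost_deflator_error")
  }
  ref <- deflator$deflator[[as.character(2017L)]]
  if (is.null(ref)) abort("deflator table does not cover the reference year 2017",
                          class = "regcost_deflator_error")
  amount_nominal * ref / unname(deflator$deflator[idx]) / deflator$fx_rate_2017
}

#' Assemble annual cost panels for every person-year under follow-up
#'
#' One row per person per calendar year overlapping the person's follow-up
#' window. Each cost component is the sum of that person-year's nominal
#' register amounts, restated in 2017 Euro. Subsidised prescription cost is
#' service cost minus out-of-pocket cost, floored at zero (a warning reports
#' floored rows). `combined_healthcare_cost` is the sum of psychiatric DRG,
#' somatic DRG, subsidised prescription and primary-care cost (out-of-pocket
#' excluded). `py` is the fraction of the calendar year covered by the
#' follow-up window.
#'
#' @param bundle a `register_bundle`.
#' @param config a [study_config()].
#' @param deflator a [deflator_table()].
#' @return a `data.table` keyed by `(person_id, year)` with the component
#'   columns in `regcost:::COST_COMPONENTS` plus `py`.
#' @export
build_cost_panels <- function(bundle, config = study_config(),
                              deflator = default_deflator_table()) {
  windows <- followup_windows(bundle$civil, config)
  yrs <- study_years(config)

  grid <- windows[, {
    y <- seq(year(start), year(end - 1L))
    .(year = y, py = year_fraction(start, end, y))
  }, by = person_id]
  grid <- grid[year %in% yrs & py > 0]

  ec <- function(x) if (is.null(x)) numeric() else x

  drg <- dcast(
    as.data.table(bundle$drg_costs)[, .(amount = sum(amount_nominal)),
                                    by = .(person_id, year, category)],
    person_id + year ~ category, value.var = "amount", fill = 0)
  for (col in DRG_CATEGORIES) if (!col %in% names(drg)) drg[, (col) := 0]

  rx <- as.data.table(bundle$prescriptions)[, .(
    rx_service = sum(service_cost_nominal),
    rx_oop = sum(out_of_pocket_nominal)
  ), by = .(person_id, year)]

  pc <- as.data.table(bundle$primary_care)[, .(
    primary = sum(amount_nominal)
  ), by = .(person_id, year)]

  inc <- as.data.table(bundle$income)[
    , c("person_id", "year", "personal_income_nominal", TRANSFER_COLUMNS),
    with = FALSE]

  panels <- Reduce(function(a, b) merge(a, b, by = c("person_id", "year"),
                                        all.x = TRUE),
                   list(grid, drg, rx, pc, inc))
  num_cols <- setdiff(names(panels), c("person_id", "year", "py"))
  for (col in num_cols) set(panels, which(is.na(panels[[col]])), col, 0)

  neg <- panels$rx_oop > panels$rx_service
  if (any(neg)) {
    warn(sprintf(
      "%d person-year(s) with out-of-pocket exceeding prescription service cost; subsidised cost floored at 0",
      sum(neg)))
  }
  panels[, rx_subsidised := pmax(rx_service - rx_oop, 0)]

  f <- to_eur2017(1, panels$year, deflator)
  panels[, `:=`(
    psych_cost = psych_drg * f,
    somatic_cost = somatic_drg * f,
    rx_subsidised_cost = rx_subsidised * f,
    rx_out_of_pocket_cost = rx_oop * f,
    primary_care_cost = primary * f,
    personal_income = personal_income_nominal * f
  )]
  for (col in TRANSFER_COLUMNS) set(panels, j = col, value = panels[[col]] * f)
  panels[, transfers_total := rowSums(.SD), .SDcols = TRANSFER_COLUMNS]
  panels[, combined_healthcare_cost :=
           psych_cost + somatic_cost + rx_subsidised_cost + primary_care_cost]
  keep <- c("person_id", "year", "py", COST_COMPONENTS)
  panels <- panels[, ..keep]
  setkey(panels, person_id, year)
  panels[]
}

#' Assemble the cost panel for one person-year
#'
#' Single person-year form of [build_cost_panels()]. Errors when the year does
#' not overlap the person's follow-up window or no deflator covers it. A
#' person-year with no register rows yields a panel of zeros.
#'
#' @param person_id person identifier.
#' @param year calendar year.
#' @param bundle a `register_bundle`.
#' @param config a [study_config()].
#' @param deflator a [deflator_table()].
#' @return a one-row panel `data.table`.
#' @export
assemble_annual_costs <- function(person_id, year, bundle,
                                  config = study_config(),
                                  deflator = default_deflator_table()) {
  pid <- person_id
  yr <- as.integer(year)
  if (!yr %in% as.integer(names(deflator$deflator))) {
    abort(paste0("no deflator for year ", yr), class = "regcost_deflator_error")
  }
  sub <- bundle
  sub$civil <- as.data.table(bundle$civil)[person_id == pid]
  if (nrow(sub$civil) == 0L) {
    abort(paste0("person '", pid, "' not in the civil register"),
          class = "regcost_validation_error")
  }
  w <- followup_windows(sub$civil, config)
  if (nrow(w) == 0L || year_fraction(w$start, w$end, yr) <= 0) {
    abort(sprintf("year %d is outside the follow-up window of person '%s'",
                  yr, pid),
          class = "regcost_window_error")
  }
  for (nm in setdiff(names(BUNDLE_FILES), "civil")) {
    sub[[nm]] <- as.data.table(bundle[[nm]])[person_id == pid]
  }
  panels <- build_cost_panels(sub, config, deflator)
  panels[year == yr]
}
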