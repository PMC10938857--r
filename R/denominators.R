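#' Population denominators by sex and age band
#'
#' Counts of persons alive and resident on a reference date, by sex and
#' 5-year attained-age band; the denominators behind per-capita estimates
#' (the reference population is the 2017 population under the defaults).
#'
#' @param persons a civil register table.
#' @param ref_date reference date.
#' @return `data.table` with columns `sex`, `age_band_lab`, `count`.
#' @export
compute_population_denominators <- function(persons,
                                            ref_date = as.Date("2017-01-01")) {
  persons <- as.data.table(persons)
  ref_date <- as.Date(ref_date)
  present <- persons[
    birth_date <= ref_date &
      (is.na(immigration_date) | immigration_date <= ref_date) &
      (is.na(emigration_date) | emigration_date > ref_date) &
      (is.na(death_date) | death_date > ref_date)]
  present[, age := as.integer(floor(as.numeric(ref_date - birth_date) / 365.25))]
  out <- present[age < 95, .(count = .N),
                 by = .(sex, age_band_lab = age_band(age))]
  setorder(out, sex, age_band_lab)
  out[]
}

#' Read or write a denominator table
#'
#' @param path file path (comma-delimited, columns `sex`, `age_band_lab`,
#'   `count`).
#' @param denominators a denominator `data.table`.
#' @return the table (read) or `path` invisibly (write).
#' @export
read_population_denominators <- function(path) {
  den <- fread(path, colClasses = c(sex = "character",
                                    age_band_lab = "character",
                                    count = "integer"))
  missing_cols <- setdiff(c("sex", "age_band_lab", "count"), names(den))
  if (length(missing_cols)) {
    schema_error(paste0("denominator file is missing column",
                        if (length(missing_cols) > 1L) "s", ": ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(den$count < 0)) {
    validation_error("denominators", "negative population count")
  }
  den
}

#' @rdname read_population_denominators
#' @export
write_population_denominators <- function(denominators, path) {
  fwrite(as.data.table(denominators), path, sep = ",", quote = FALSE)
  invisible(path)
}
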