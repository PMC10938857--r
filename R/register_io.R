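# Readers, writers and validation for the six register tables.
#
# File dialect: UTF-8, comma-delimited, header row mandatory, ISO-8601 dates,
# missing optional dates encoded as the empty string. Row order is preserved.

#' Register schemas
#'
#' Column names and types of the six register tables handled by the package:
#' `civil` (one row per person: sex, birth and censoring dates), `psychiatric`
#' (hospital contacts with ICD-10 codes), `drg_costs` (annual psychiatric and
#' somatic hospital DRG tariff sums), `prescriptions` (annual prescription
#' service and out-of-pocket cost), `primary_care` (annual primary-sector
#' service cost by provider type) and `income` (annual personal income and the
#' nine public transfer components). Monetary columns are nominal local
#' currency of the recorded year.
#'
#' @return named list; each element has `$columns` (name -> type, where type is
#'   one of `"character"`, `"date"`, `"date_opt"`, `"integer"`, `"numeric"`).
#' @export
register_schemas <- function() {
  list(
    civil = list(columns = c(
      person_id = "character", sex = "character", birth_date = "date",
      immigration_date = "date_opt", emigration_date = "date_opt",
      death_date = "date_opt"
    )),
    psychiatric = list(columns = c(
      person_id = "character", event_date = "date", icd10_code = "character",
      contact_type = "character"
    )),
    drg_costs = list(columns = c(
      person_id = "character", year = "integer", category = "character",
      amount_nominal = "numeric"
    )),
    prescriptions = list(columns = c(
      person_id = "character", year = "integer",
      service_cost_nominal = "numeric", out_of_pocket_nominal = "numeric"
    )),
    primary_care = list(columns = c(
      person_id = "character", year = "integer", provider_type = "character",
      amount_nominal = "numeric"
    )),
    income = list(columns = c(
      person_id = "character", year = "integer",
      personal_income_nominal = "numeric",
      setNames(rep("numeric", length(TRANSFER_COLUMNS)), TRANSFER_COLUMNS)
    ))
  )
}

schema_error <- function(msg) abort(msg, class = "regcost_schema_error")

validation_error <- function(register, problems) {
  shown <- head(problems, 5L)
  msg <- paste0(
    "validation failed for register '", register, "' (",
    length(problems), " problem", if (length(problems) > 1L) "s", "):\n",
    paste0("  ", shown, collapse = "\n"),
    if (length(problems) > length(shown)) "\n  ..."
  )
  abort(msg, class = "regcost_validation_error")
}

get_schema <- function(schema_name) {
  schemas <- register_schemas()
  if (!schema_name %in% names(schemas)) {
    schema_error(paste0(
      "unknown schema '", schema_name, "'; expected one of: ",
      paste(names(schemas), collapse = ", ")
    ))
  }
  schemas[[schema_name]]
}

parse_iso_date <- function(x, col, register, optional, problems_env) {
  x[!nzchar(x)] <- NA_character_
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad)) {
    problems_env$problems <- c(problems_env$problems, sprintf(
      "row %d: column '%s' is not an ISO-8601 date ('%s')", bad, col, x[bad]
    ))
  }
  if (!optional) {
    miss <- which(is.na(x))
    if (length(miss)) {
      problems_env$problems <- c(problems_env$problems, sprintf(
        "row %d: required date column '%s' is missing", miss, col
      ))
    }
  }
  d
}

# Coerce an all-character table to schema types, collecting parse problems.
coerce_register <- function(tbl, schema_name) {
  schema <- get_schema(schema_name)
  cols <- schema$columns
  missing_cols <- setdiff(names(cols), names(tbl))
  if (length(missing_cols)) {
    schema_error(paste0(
      "register '", schema_name, "' is missing required column",
      if (length(missing_cols) > 1L) "s", ": ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- as.data.table(tbl)[, names(cols), with = FALSE]
  env <- new.env()
  env$problems <- character()
  for (col in names(cols)) {
    type <- cols[[col]]
    x <- out[[col]]
    if (type %in% c("date", "date_opt")) {
      if (!inherits(x, "Date")) {
        x <- parse_iso_date(as.character(x), col, schema_name,
                            optional = type == "date_opt", problems_env = env)
      }
    } else if (type == "integer") {
      x2 <- suppressWarnings(as.integer(x))
      bad <- which(is.na(x2) & !is.na(x))
      if (length(bad)) {
        env$problems <- c(env$problems, sprintf(
          "row %d: column '%s' is not an integer", bad, col))
      }
      x <- x2
    } else if (type == "numeric") {
      x2 <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(x2) & !is.na(x))
      if (length(bad)) {
        env$problems <- c(env$problems, sprintf(
          "row %d: column '%s' is not numeric", bad, col))
      }
      x <- x2
    } else {
      x <- as.character(x)
    }
    set(out, j = col, value = x)
  }
  if (length(env$problems)) validation_error(schema_name, env$problems)
  out[]
}

check_nonneg <- function(tbl, cols, problems) {
  for (col in cols) {
    bad <- which(!is.na(tbl[[col]]) & tbl[[col]] < 0)
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: %s is negative", bad, col))
    }
    miss <- which(is.na(tbl[[col]]))
    if (length(miss)) {
      problems <- c(problems, sprintf("row %d: %s is missing", miss, col))
    }
  }
  problems
}

#' Validate a register table against its schema invariants
#'
#' Checks every row of a typed register table against the invariants of its
#' schema (date orderings in the civil register, ICD-10 code syntax and contact
#' types in the psychiatric register, non-negative amounts and category levels
#' in the cost registers, one row per person-year and all nine transfer
#' components in the income register). Errors of class
#' `regcost_validation_error` name the offending rows and rules.
#'
#' @param tbl a typed register table (as returned by [read_register()]).
#' @param schema_name one of the names of [register_schemas()].
#' @return `tbl`, invisibly, when valid.
#' @export
validate_register <- function(tbl, schema_name) {
  schema <- get_schema(schema_name)
  tbl <- as.data.table(tbl)
  problems <- character()

  if (schema_name == "civil") {
    dup <- which(duplicated(tbl$person_id))
    if (length(dup)) {
      problems <- c(problems, sprintf(
        "row %d: duplicated person_id '%s'", dup, tbl$person_id[dup]))
    }
    bad_sex <- which(!tbl$sex %in% c("female", "male"))
    if (length(bad_sex)) {
      problems <- c(problems, sprintf(
        "row %d: sex must be 'female' or 'male'", bad_sex))
    }
    for (col in c("immigration_date", "emigration_date", "death_date")) {
      bad <- which(!is.na(tbl[[col]]) & tbl[[col]] < tbl$birth_date)
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "row %d: %s precedes birth_date", bad, col))
      }
    }
    # death, when present, is the person's final event
    for (col in c("immigration_date", "emigration_date")) {
      bad <- which(!is.na(tbl$death_date) & !is.na(tbl[[col]]) &
                     tbl[[col]] > tbl$death_date)
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "row %d: %s falls after death_date", bad, col))
      }
    }
  } else if (schema_name == "psychiatric") {
    bad_code <- which(!grepl("^[A-Z][0-9]{2,}(\\.[0-9]+)?$", tbl$icd10_code))
    if (length(bad_code)) {
      problems <- c(problems, sprintf(
        "row %d: malformed ICD-10 code '%s'", bad_code, tbl$icd10_code[bad_code]))
    }
    bad_ct <- which(!tbl$contact_type %in% CONTACT_TYPES)
    if (length(bad_ct)) {
      problems <- c(problems, sprintf(
        "row %d: contact_type must be one of %s", bad_ct,
        paste(CONTACT_TYPES, collapse = "/")))
    }
  } else if (schema_name == "drg_costs") {
    bad_cat <- which(!tbl$category %in% DRG_CATEGORIES)
    if (length(bad_cat)) {
      problems <- c(problems, sprintf(
        "row %d: category must be one of %s", bad_cat,
        paste(DRG_CATEGORIES, collapse = "/")))
    }
    problems <- check_nonneg(tbl, "amount_nominal", problems)
  } else if (schema_name == "prescriptions") {
    problems <- check_nonneg(
      tbl, c("service_cost_nominal", "out_of_pocket_nominal"), problems)
  } else if (schema_name == "primary_care") {
    bad_pt <- which(!tbl$provider_type %in% PRIMARY_CARE_PROVIDERS)
    if (length(bad_pt)) {
      problems <- c(problems, sprintf(
        "row %d: unknown provider_type '%s'", bad_pt, tbl$provider_type[bad_pt]))
    }
    problems <- check_nonneg(tbl, "amount_nominal", problems)
  } else if (schema_name == "income") {
    problems <- check_nonneg(
      tbl, c("personal_income_nominal", TRANSFER_COLUMNS), problems)
    dup <- which(duplicated(tbl[, .(person_id, year)]))
    if (length(dup)) {
      problems <- c(problems, sprintf(
        "row %d: more than one income record for person '%s' in %d",
        dup, tbl$person_id[dup], tbl$year[dup]))
    }
  }

  if (length(problems)) validation_error(schema_name, problems)
  invisible(tbl)
}

#' Read a register file
#'
#' Reads a delimited register file, checks the header against the schema and
#' validates every row. Missing required columns raise a
#' `regcost_schema_error`; rows violating a type invariant raise a
#' `regcost_validation_error` naming the row and rule.
#'
#' @param path path to a UTF-8 comma-delimited file with a header row.
#' @param schema_name one of the names of [register_schemas()].
#' @return a typed `data.table` in file row order.
#' @export
read_register <- function(path, schema_name) {
  if (!file.exists(path)) schema_error(paste0("file not found: ", path))
  raw <- fread(path, colClasses = "character", sep = ",", header = TRUE,
               na.strings = NULL, encoding = "UTF-8")
  tbl <- coerce_register(raw, schema_name)
  validate_register(tbl, schema_name)
  tbl
}

#' Write a register file
#'
#' Inverse of [read_register()]: ISO-8601 dates, empty string for missing
#' optional dates, comma-delimited, header row. `write_register()` followed by
#' [read_register()] reproduces the table exactly.
#'
#' @param tbl a typed register table.
#' @param path output file path.
#' @param schema_name one of the names of [register_schemas()].
#' @return `path`, invisibly.
#' @export
write_register <- function(tbl, path, schema_name) {
  schema <- get_schema(schema_name)
  out <- as.data.table(tbl)[, names(schema$columns), with = FALSE]
  for (col in names(schema$columns)) {
    if (schema$columns[[col]] %in% c("date", "date_opt")) {
      set(out, j = col, value = format(out[[col]], "%Y-%m-%d"))
    }
  }
  fwrite(out, path, sep = ",", na = "", quote = FALSE)
  invisible(path)
}

BUNDLE_FILES <- c(
  civil = "civil.csv", psychiatric = "psychiatric.csv",
  drg_costs = "drg_costs.csv", prescriptions = "prescriptions.csv",
  primary_care = "primary_care.csv", income = "income.csv"
)

#' Read or write a complete register bundle
#'
#' A register bundle is a directory holding the six register files
#' (`civil.csv`, `psychiatric.csv`, `drg_costs.csv`, `prescriptions.csv`,
#' `primary_care.csv`, `income.csv`). Reading validates every table.
#'
#' @param dir directory path.
#' @return for `read_register_bundle()`, a named list of typed tables with
#'   class `register_bundle`; for `write_register_bundle()`, `dir` invisibly.
#' @export
read_register_bundle <- function(dir) {
  bundle <- lapply(names(BUNDLE_FILES), function(nm) {
    read_register(file.path(dir, BUNDLE_FILES[[nm]]), nm)
  })
  names(bundle) <- names(BUNDLE_FILES)
  structure(bundle, class = "register_bundle")
}

#' @param bundle a named list of the six register tables.
#' @rdname read_register_bundle
#' @export
write_register_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(BUNDLE_FILES)) {
    write_register(bundle[[nm]], file.path(dir, BUNDLE_FILES[[nm]]), nm)
  }
  invisible(dir)
}

#' Validate every table of a register bundle
#'
#' Cross-table checks in addition to per-table validation: every person
#' referenced by an event or cost table must exist in the civil register.
#'
#' @param bundle a `register_bundle`.
#' @return `bundle`, invisibly, when valid.
#' @export
validate_register_bundle <- function(bundle) {
  for (nm in names(BUNDLE_FILES)) validate_register(bundle[[nm]], nm)
  known <- bundle$civil$person_id
  for (nm in setdiff(names(BUNDLE_FILES), "civil")) {
    unknown <- setdiff(unique(bundle[[nm]]$person_id), known)
    if (length(unknown)) {
      validation_error(nm, sprintf(
        "person_id '%s' not present in the civil register", head(unknown, 5L)))
    }
  }
  invisible(bundle)
}

#' @export
print.register_bundle <- function(x, ...) {
  cat("<register_bundle>\n")
  for (nm in names(BUNDLE_FILES)) {
    cat(sprintf("  %-13s %8d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
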