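# The disorder-definition catalogue: ICD-10 code prefixes and assumed earliest
# onset age for each of the 18 disorder types, plus the "any mental disorder"
# aggregate defined as the union of the 18 code sets.
#
# The bundled code sets are plausible placeholders following common
# GBD-style groupings of the ICD-10 F chapter; analyses of real register
# extracts should supply their own catalogue file.

DISORDER_NAMES <- c(
  "alcohol-use disorder", "opioid-use disorder", "cannabis-use disorder",
  "cocaine-use disorder", "amphetamine-use disorder", "other drug-use disorders",
  "schizophrenia", "bipolar disorder", "major depressive disorder",
  "dysthymia", "anxiety disorders", "anorexia nervosa", "bulimia nervosa",
  "personality disorders", "intellectual disabilities",
  "autism spectrum disorders", "ADHD", "conduct disorders"
)

ANY_DISORDER <- "any mental disorder"

#' The bundled disorder catalogue
#'
#' Eighteen named disorder definitions plus the `"any mental disorder"`
#' aggregate, whose code set is the union of the 18. Each definition carries a
#' set of ICD-10 code prefixes (matching is by prefix, so `"F32"` covers
#' `"F32.1"`) and an assumed earliest age of onset in years: diagnosis events
#' recorded at younger ages are ignored when identifying cases.
#'
#' @return a `data.table` with columns `disorder_name`, `icd10_codes`
#'   (list column of character vectors), `earliest_onset_age`, `is_aggregate`.
#' @export
default_disorder_catalogue <- function() {
  def <- list(
    "alcohol-use disorder"       = list(c("F10"), 12),
    "opioid-use disorder"        = list(c("F11"), 12),
    "cannabis-use disorder"      = list(c("F12"), 10),
    "cocaine-use disorder"       = list(c("F14"), 12),
    "amphetamine-use disorder"   = list(c("F15"), 10),
    "other drug-use disorders"   = list(c("F13", "F16", "F18", "F19"), 10),
    "schizophrenia"              = list(c("F20"), 10),
    "bipolar disorder"           = list(c("F30", "F31"), 10),
    "major depressive disorder"  = list(c("F32", "F33"), 5),
    "dysthymia"                  = list(c("F34.1"), 5),
    "anxiety disorders"          = list(c("F40", "F41"), 3),
    "anorexia nervosa"           = list(c("F50.0", "F50.1"), 5),
    "bulimia nervosa"            = list(c("F50.2", "F50.3"), 8),
    "personality disorders"      = list(c("F60", "F61"), 12),
    "intellectual disabilities"  = list(c("F70", "F71", "F72", "F73", "F78", "F79"), 0),
    "autism spectrum disorders"  = list(c("F84"), 1),
    "ADHD"                       = list(c("F90"), 3),
    "conduct disorders"          = list(c("F91"), 2)
  )
  stopifnot(identical(names(def), DISORDER_NAMES))
  cat <- data.table(
    disorder_name = names(def),
    icd10_codes = lapply(def, `[[`, 1L),
    earliest_onset_age = vapply(def, `[[`, numeric(1), 2L),
    is_aggregate = FALSE
  )
  any_row <- data.table(
    disorder_name = ANY_DISORDER,
    icd10_codes = list(sort(unique(unlist(cat$icd10_codes)))),
    earliest_onset_age = min(cat$earliest_onset_age),
    is_aggregate = TRUE
  )
  rbind(cat, any_row)
}

validate_catalogue <- function(cat) {
  problems <- character()
  dup <- unique(cat$disorder_name[duplicated(cat$disorder_name)])
  if (length(dup)) {
    problems <- c(problems, sprintf("duplicated disorder name '%s'", dup))
  }
  empty <- which(lengths(cat$icd10_codes) == 0L)
  if (length(empty)) {
    problems <- c(problems, sprintf(
      "empty ICD-10 code set for '%s'", cat$disorder_name[empty]))
  }
  if (any(cat$earliest_onset_age < 0)) {
    problems <- c(problems, "earliest_onset_age must be >= 0")
  }
  agg <- cat[is_aggregate == TRUE]
  if (nrow(agg) == 1L) {
    union_codes <- sort(unique(unlist(cat[is_aggregate == FALSE]$icd10_codes)))
    if (!identical(sort(unlist(agg$icd10_codes)), union_codes)) {
      problems <- c(problems, paste0(
        "'", agg$disorder_name, "' code set is not the union of the named ",
        "disorder code sets"))
    }
  }
  if (length(problems)) validation_error("disorder catalogue", problems)
  invisible(cat)
}

#' Load a disorder catalogue from a YAML file
#'
#' The file holds a `disorders:` list of entries with `name`, `icd10` (list of
#' code prefixes) and `earliest_onset_age`, optionally flagged
#' `aggregate: true` for the any-disorder union. Duplicate names, empty code
#' sets and an aggregate that is not the union of the named sets are errors.
#' With `path = NULL` the bundled default catalogue file is loaded.
#'
#' @param path path to a catalogue YAML file, or `NULL` for the bundled one.
#' @return a catalogue `data.table` (see [default_disorder_catalogue()]).
#' @export
load_disorder_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "disorder_catalogue.yaml", package = "regcost")
  }
  if (!file.exists(path)) schema_error(paste0("file not found: ", path))
  spec <- yaml::read_yaml(path)
  if (is.null(spec$disorders)) {
    schema_error("catalogue file has no 'disorders' entry")
  }
  cat <- rbindlist(lapply(spec$disorders, function(d) {
    data.table(
      disorder_name = d$name,
      icd10_codes = list(as.character(unlist(d$icd10))),
      earliest_onset_age = as.numeric(d$earliest_onset_age),
      is_aggregate = isTRUE(d$aggregate)
    )
  }))
  validate_catalogue(cat)
  cat
}

#' Write a disorder catalogue to a YAML file
#'
#' @param cat a catalogue `data.table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_disorder_catalogue <- function(cat, path) {
  entries <- lapply(seq_len(nrow(cat)), function(i) {
    e <- list(
      name = cat$disorder_name[[i]],
      icd10 = as.list(cat$icd10_codes[[i]]),
      earliest_onset_age = cat$earliest_onset_age[[i]]
    )
    if (cat$is_aggregate[[i]]) e$aggregate <- TRUE
    e
  })
  yaml::write_yaml(list(disorders = entries), path)
  invisible(path)
}

# Prefix matching with ICD-10 chapter/block semantics: an event code matches a
# definition if it starts with any of the definition's prefixes, so sub-codes
# of the Danish dialect ("F32.11") do not defeat matching against "F32".
icd_prefix_match <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

get_definition <- function(catalogue, disorder) {
  row <- catalogue[disorder_name == disorder]
  if (nrow(row) != 1L) {
    abort(paste0("unknown disorder name '", disorder, "'"),
          class = "regcost_unknown_disorder")
  }
  row
}
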