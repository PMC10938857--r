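# Pipeline orchestration and figure-style ranking tables.

#' Rank disorders by an estimate
#'
#' Orders disorders by the absolute value of the chosen measure, descending,
#' ties broken alphabetically. For `combined_healthcare_cost` the four
#' contributing components (psychiatric DRG, somatic DRG, subsidised
#' prescriptions, primary care) are attached as breakdown columns that sum to
#' the ranked value.
#'
#' @param estimates output of [aggregate_estimates()].
#' @param measure one of `"nationwide_annual"`, `"per_case_annual"`,
#'   `"per_capita_annual"`.
#' @param cost_kind `"absolute"` or `"excess"`.
#' @param component ranked component (default combined healthcare cost).
#' @return a `data.table` in rank order with columns `rank`, `disorder_name`,
#'   `value` (plus breakdown columns where applicable).
#' @export
rank_disorders <- function(estimates, measure, cost_kind,
                           component = "combined_healthcare_cost") {
  if (!measure %in% MEASURES) {
    abort(paste0("unknown measure '", measure, "'; expected one of: ",
                 paste(MEASURES, collapse = ", ")),
          class = "regcost_measure_error")
  }
  if (!cost_kind %in% c("absolute", "excess")) {
    abort("cost_kind must be 'absolute' or 'excess'",
          class = "regcost_measure_error")
  }
  check_component(component)
  est <- as.data.table(estimates)
  m <- measure; ck <- cost_kind; comp <- component
  sub <- est[measure == m & cost_kind == ck & stratum_type == "overall" &
               component == comp]
  sub <- sub[order(-abs(value), disorder_name)]   # alphabetical tie-break
  ranked <- sub[, .(disorder_name, value)]
  if (component == "combined_healthcare_cost") {
    parts <- c("psych_cost", "somatic_cost", "rx_subsidised_cost",
               "primary_care_cost")
    br <- est[measure == m & cost_kind == ck & stratum_type == "overall" &
                component %in% parts,
              .(disorder_name, component, value)]
    if (nrow(br)) {
      br <- dcast(br, disorder_name ~ component, value.var = "value")
      ranked <- br[ranked, on = "disorder_name"]
      setcolorder(ranked, c("disorder_name", "value",
                            intersect(parts, names(ranked))))
    }
  }
  ranked[, rank := seq_len(.N)]
  setcolorder(ranked, c("rank", "disorder_name", "value"))
  ranked[]
}

coerce_study_config <- function(study) {
  if (is.null(study)) return(study_config())
  for (k in c("followup_start", "followup_end")) {
    if (!is.null(study[[k]])) study[[k]] <- as.Date(study[[k]])
  }
  do.call(study_config, study)
}

coerce_deflator <- function(defl) {
  if (is.null(defl)) return(default_deflator_table())
  deflator_table(unlist(defl$deflator), defl$fx_rate_2017)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (optional) -> cohort -> costing -> estimation ->
#' reports, writing all output tables and a run log to the output directory.
#' The configuration is a nested list (or a YAML file holding one) with
#' optional entries `seed`, `simulate` (arguments to [sim_params()]),
#' `input_dir` (a register-bundle directory, used when `simulate` is absent),
#' `study` (arguments to [study_config()]), `catalogue` (path to a catalogue
#' file), `deflator` (`deflator` mapping and `fx_rate_2017`), `denominators`
#' (path) and `output_dir`. Reruns with the same configuration produce
#' byte-identical outputs.
#'
#' @param config a list or the path to a YAML file.
#' @param output_dir overrides the configured output directory.
#' @return invisibly, a list with the estimates, profile, matched sets,
#'   rankings and the output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort("no output directory configured", class = "regcost_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(cfg)
  log_lines <- c(sprintf("config_hash: %s", cfg_hash))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "regcost_pipeline_error")
    })
  }

  seed <- cfg$seed %||% 1L
  config_s <- stage("config", coerce_study_config(cfg$study))
  config_s$seed <- as.integer(seed)
  catalogue <- stage("catalogue", if (is.null(cfg$catalogue)) {
    default_disorder_catalogue()
  } else load_disorder_catalogue(cfg$catalogue))
  deflator <- stage("deflator", coerce_deflator(cfg$deflator))
  log_lines <- c(log_lines, sprintf("seed: %d", as.integer(seed)))

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- as.integer(seed)
    sim_args$catalogue <- catalogue
    sim_args$deflator <- deflator
    sim <- stage("simulate", simulate_registers(do.call(sim_params, sim_args)))
    bundle <- sim$bundle
    log_lines <- c(log_lines, sprintf("simulated_persons: %d", nrow(bundle$civil)))
  } else if (!is.null(cfg$input_dir)) {
    bundle <- stage("read", read_register_bundle(cfg$input_dir))
  } else {
    abort("config needs either 'simulate' or 'input_dir'",
          class = "regcost_config_error")
  }
  stage("validate", validate_register_bundle(bundle))

  denominators <- stage("denominators", if (is.null(cfg$denominators)) {
    compute_population_denominators(bundle$civil)
  } else read_population_denominators(cfg$denominators))

  ms <- stage("cohort", suppressWarnings(
    build_matched_cohort(bundle$civil, bundle$psychiatric, catalogue, config_s)))
  cc <- attr(ms, "case_counts")
  log_lines <- c(log_lines,
                 sprintf("cases[%s]: %d", cc$disorder_name, cc$n_cases),
                 sprintf("deficient_sets: %d",
                         nrow(attr(ms, "deficient_sets"))))

  panels <- stage("costing", suppressWarnings(
    build_cost_panels(bundle, config_s, deflator)))
  estimates <- stage("estimation",
                     aggregate_estimates(ms, panels, denominators, config_s))
  profile <- stage("profile",
                   years_since_diagnosis_profile(ms, panels, config_s))
  log_lines <- c(log_lines,
                 sprintf("skipped_set_years: %d",
                         nrow(attr(estimates, "skipped_set_years"))))

  rankings <- stage("report", list(
    nationwide_absolute = rank_disorders(estimates, "nationwide_annual", "absolute"),
    nationwide_excess = rank_disorders(estimates, "nationwide_annual", "excess"),
    per_case_absolute = rank_disorders(estimates, "per_case_annual", "absolute"),
    per_case_excess = rank_disorders(estimates, "per_case_annual", "excess")
  ))

  header <- sprintf("# config_hash=%s", cfg_hash)
  write_table <- function(tbl, file) {
    path <- file.path(out_dir, file)
    writeLines(header, path)
    fwrite(tbl, path, sep = ",", quote = FALSE, append = TRUE,
           col.names = TRUE)
    path
  }
  paths <- c(
    write_table(estimates, "estimates.csv"),
    write_table(profile, "profile_years_since_diagnosis.csv"),
    vapply(names(rankings), function(nm) {
      write_table(rankings[[nm]], paste0("ranking_", nm, ".csv"))
    }, character(1)),
    {
      p <- file.path(out_dir, "matched_sets.csv")
      write_matched_sets(ms, p)
      p
    },
    {
      p <- file.path(out_dir, "run_log.txt")
      writeLines(log_lines, p)
      p
    }
  )
  invisible(list(estimates = estimates, profile = profile, matched_sets = ms,
                 rankings = rankings, bundle = bundle, panels = panels,
                 denominators = denominators, paths = paths,
                 log = log_lines))
}
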