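# End-to-end orchestration: simulate (or load) -> discover -> associate,
# with machine-readable JSON reports and a plain-text summary.

#' Run the simulate-discover-associate pipeline
#'
#' Generates (or loads) the family exome and case-control cohort, runs the
#' discovery cascade, performs the exact association analyses (case versus
#' control and case versus background population), compares covariates
#' between arms, fits the logistic confounding model (status on height,
#' weight and carrier genotype), and tests subcohort homogeneity.  All
#' artifacts and a JSON report are written under `out_dir`.  The run is
#' deterministic given the config seed; the report's timestamp is isolated
#' in a single `generated_at` field.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory; created if needed.  `NULL` skips writing.
#' @param stages character subset of `c("discover", "associate")`; the
#'   simulation stage always runs unless `family`/`cohort` are supplied.
#' @param family,cohort optional pre-built `family_dataset` /
#'   `cohort_dataset`, e.g. reloaded from a previous run's artifacts; when
#'   given, simulation is skipped for that input.
#' @param method,ci_method,level exact-test settings passed to
#'   [associate_table()].
#' @param strict_deleterious passed to [run_cascade()].
#' @param quiet suppress progress messages (they go to `stderr`).
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         stages = c("discover", "associate"),
                         family = NULL, cohort = NULL,
                         method = "minlike", ci_method = "minlike",
                         level = 0.95, strict_deleterious = FALSE,
                         quiet = TRUE) {
  config <- validate_config(config)
  stages <- match.arg(stages, c("discover", "associate"), several.ok = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }

  say("simulate", "building synthetic inputs (seed ", config$seed, ")")
  family <- family %||% generate_family_exomes(config)
  cohort <- cohort %||% generate_case_control_cohort(config)

  report <- list(
    provenance = list(tool = "vtevar",
                      version = as.character(utils::packageVersion("vtevar")),
                      seed = config$seed, config_hash = config_hash(config)),
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if ("discover" %in% stages) {
    say("discover", "running filter cascade")
    disc <- run_cascade(family, strict_deleterious = strict_deleterious)
    report$discovery <- list(
      trace = disc$trace$counts,
      candidates = as.data.frame(disc$candidates),
      truth = family$truth %||% NA_character_,
      recovered = identical(sort(disc$candidates$id),
                            sort(family$truth %||% character())))
  }

  if ("associate" %in% stages) {
    say("associate", "exact association and covariate analyses")
    subj <- cohort$subjects
    case_ac <- allele_counts(subj$genotype[subj$status == "case"])
    ctrl_ac <- allele_counts(subj$genotype[subj$status == "control"])
    bg_ac <- allele_count(config$background_carriers,
                          2L * config$background_n)
    tab_cc <- build_table(case_ac, ctrl_ac)
    tab_cb <- build_table(case_ac, bg_ac)
    assoc <- list(
      case_control = assoc_section(tab_cc, case_ac, ctrl_ac, method,
                                   ci_method, level),
      case_background = assoc_section(tab_cb, case_ac, bg_ac, method,
                                      ci_method, level))

    cov_cols <- c("sex", "age", "height", "weight")
    covariates <- compare_covariates(
      subj[subj$status == "case", cov_cols],
      subj[subj$status == "control", cov_cols])

    lf <- logistic_fit(subj[, c("height", "weight", "genotype")],
                       subj$status == "case")
    logistic <- if (lf$separated) {
      list(separated = TRUE, n_excluded = lf$n_excluded)
    } else {
      list(separated = FALSE, coefficients = lf$coefficients,
           converged = lf$converged, n_used = lf$n_used,
           n_excluded = lf$n_excluded)
    }

    sub_tabs <- lapply(split(subj, subj$subcohort), function(s) {
      build_table(allele_counts(s$genotype[s$status == "case"]),
                  allele_counts(s$genotype[s$status == "control"]))
    })
    homogeneity <- subcohort_homogeneity(sub_tabs, method = method)

    report$association <- assoc
    report$covariates <- covariates
    report$logistic <- logistic
    report$homogeneity <- homogeneity
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) {
    say("report", "writing artifacts to ", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_family_dataset(family, out_dir)
    write_covariate_table(cohort$subjects, file.path(out_dir, "cohort.tsv"))
    write_report(report, file.path(out_dir, "report.json"))
    writeLines(format_report(report), file.path(out_dir, "summary.txt"))
  }
  report
}

assoc_section <- function(tab, ac1, ac2, method, ci_method, level) {
  r <- associate_table(tab, method = method, ci_method = ci_method,
                       level = level)
  list(table = as.integer(r$table), maf = c(maf(ac1), maf(ac2)),
       p_value = r$p_value, p_method = r$p_method,
       or_sample = r$or_sample, or_cmle = r$or_cmle,
       ci = r$ci, ci_level = r$ci_level, ci_method = r$ci_method)
}

# Stable hash of the configuration (seed included) for provenance.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @rdname run_pipeline
#' @param report a `pipeline_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

format_report <- function(report) {
  out <- c("vtevar pipeline report",
           sprintf("seed: %s  config: %s", report$provenance$seed,
                   report$provenance$config_hash))
  if (!is.null(report$discovery)) {
    tr <- report$discovery$trace
    out <- c(out, "", "discovery cascade:",
             sprintf("  %-20s %5d -> %5d", tr$stage, tr$n_in, tr$n_out),
             sprintf("  candidates: %s",
                     paste(report$discovery$candidates$id, collapse = ", ")))
  }
  if (!is.null(report$association)) {
    fmt <- function(name, s) sprintf(
      "  %-16s P = %.4g (%s), OR = %.3g, %d%% CI %.3g-%.3g (%s)",
      name, s$p_value, s$p_method, s$or_sample, round(100 * s$ci_level),
      s$ci[1], s$ci[2], s$ci_method)
    out <- c(out, "", "association:",
             fmt("case-control", report$association$case_control),
             fmt("case-background", report$association$case_background))
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
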