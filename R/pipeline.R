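`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the phenotype pipeline end to end
#'
#' Orchestrates simulate (optional) -> screen -> match -> validate as one
#' reproducible run. The configuration is a list (or path to a YAML file)
#' with elements:
#' \describe{
#'   \item{claims_dir}{directory with the four claims CSVs, or}
#'   \item{simulate}{arguments for [cohort_spec()] (mutually exclusive
#'     with `claims_dir`); the generated claims and gold labels are
#'     written next to the results.}
#'   \item{out_dir}{output directory (required).}
#'   \item{params}{optional overrides for [phenotype_params()].}
#'   \item{gold}{optional path to a gold-label CSV for validation.}
#' }
#' Emits `cohort.csv`, `report.json` (stage funnel plus validation
#' metrics when gold labels are available) and logs the stage counts.
#'
#' @param config list or YAML path.
#' @param quiet suppress progress messages.
#' @return An object of class `bnhl_run`: list with `fit`, `report`,
#'   `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config must name out_dir")
  say <- function(...) if (!quiet) message(sprintf(...))
  params <- do.call(phenotype_params, config$params %||% list())
  gold <- NULL
  if (!is.null(config$simulate)) {
    spec <- do.call(cohort_spec, config$simulate)
    say("simulate: generating %d synthetic patients (seed %d)",
        spec$n_patients, spec$seed)
    sim <- simulate_claims(spec, params = params)
    claims <- sim$claims
    gold <- sim$gold
  } else {
    if (is.null(config$claims_dir))
      stop("config must name claims_dir or simulate")
    if (!dir.exists(config$claims_dir))
      stop("claims directory not found: ", config$claims_dir)
    claims <- read_claims(config$claims_dir)
    if (!is.null(config$gold))
      gold <- utils::read.csv(config$gold, stringsAsFactors = FALSE)
  }
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  fit <- bnhl_phenotype(claims, params = params)
  say("screen: %d patients, %d passed code screen, %d passed billing filter",
      fit$counts["patients"], fit$counts["code_screen"],
      fit$counts["billing_filter"])
  say("match: %d patients included in the cohort", fit$counts["included"])
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(fit$decisions, cohort_path)
  report <- list(counts = as.list(fit$counts))
  if (!is.null(gold)) {
    if (!is.null(config$simulate)) {
      utils::write.csv(gold, file.path(config$out_dir, "gold_labels.csv"),
                       row.names = FALSE)
      write_claims(claims, config$out_dir)
    }
    report$validation <- lapply(
      c(code_screen = "code_screen", full_pipeline = "full_pipeline"),
      function(st) {
        tab <- build_table(fit, gold, stage = st)
        se <- sensitivity(tab)
        pv <- ppv(tab)
        list(tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
             sensitivity = se$point,
             sensitivity_ci = c(se$ci_low, se$ci_high),
             ppv = pv$point, ppv_ci = c(pv$ci_low, pv$ci_high))
      })
    say("validate: full-pipeline sensitivity %.1f%%, PPV %.1f%%",
        100 * report$validation$full_pipeline$sensitivity,
        100 * report$validation$full_pipeline$ppv)
  }
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  structure(list(fit = fit, report = report,
                 paths = c(cohort = cohort_path, report = report_path)),
            class = "bnhl_run")
}

#' @export
print.bnhl_run <- function(x, ...) {
  print(x$fit)
  cat("artifacts:\n")
  for (nm in names(x$paths)) cat(sprintf("  %s: %s\n", nm, x$paths[nm]))
  invisible(x)
}
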