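#' Build a validation contingency table against gold labels
#'
#' Crosses phenotype decisions with gold-standard labels. A true positive
#' is an included patient whose truth is `de_novo_bnhl`; a false positive
#' is an included patient with any other truth; a false negative is a
#' true de novo B-NHL patient who was excluded at any stage (or never
#' screened in). True negatives are counted too but carry no headline
#' metric, since the validation design reviews screen-positives plus a
#' registry of known cases.
#'
#' @param decisions a `bnhl_phenotype` fit or its decisions data.frame.
#' @param gold gold-label data.frame with `institution_id`, `patient_id`,
#'   `truth`.
#' @param stage `"full_pipeline"` (default) counts inclusion after
#'   chemotherapy review; `"code_screen"` counts passing the
#'   diagnosis-code screen only (step 1).
#' @return An object of class `bnhl_validation_table`: list with `tp`,
#'   `fp`, `fn`, `tn`, `stage`.
#' @export
build_table <- function(decisions, gold,
                        stage = c("full_pipeline", "code_screen")) {
  stage <- match.arg(stage)
  fit <- NULL
  if (inherits(decisions, "bnhl_phenotype")) {
    fit <- decisions
    decisions <- fit$decisions
  }
  kd <- patient_key(decisions)
  kg <- patient_key(gold)
  if (!setequal(kd, kg) || anyDuplicated(kd) || anyDuplicated(kg))
    stop("decisions and gold labels must cover the same patients exactly once")
  g <- gold[match(kd, kg), ]
  pos <- if (stage == "code_screen") {
    if (is.null(fit))
      stop("stage = 'code_screen' requires a bnhl_phenotype fit")
    fit$screen$passed_code_screen[match(kd, patient_key(fit$screen))]
  } else decisions$included
  truth_pos <- g$truth == "de_novo_bnhl"
  validation_table(tp = sum(pos & truth_pos),
                   fp = sum(pos & !truth_pos),
                   fn = sum(!pos & truth_pos),
                   tn = sum(!pos & !truth_pos),
                   stage = stage)
}

#' @rdname build_table
#' @param tp,fp,fn,tn non-negative counts (`tn` optional).
#' @export
validation_table <- function(tp, fp, fn, tn = NA_integer_,
                             stage = "full_pipeline") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, is.na(tn) || tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn), stage = stage),
            class = "bnhl_validation_table")
}

#' @export
print.bnhl_validation_table <- function(x, ...) {
  cat(sprintf("Validation table (%s): TP=%d FP=%d FN=%d%s\n", x$stage,
              x$tp, x$fp, x$fn,
              if (!is.na(x$tn)) sprintf(" TN=%d", x$tn) else ""))
  invisible(x)
}

binom_ci <- function(x, n, level, method) {
  if (method == "clopper-pearson") {
    stats::binom.test(x, n, conf.level = level)$conf.int
  } else {
    suppressWarnings(
      stats::prop.test(x, n, conf.level = level, correct = FALSE)$conf.int)
  }
}

accuracy_estimate <- function(metric, x, n, level, method) {
  if (n <= 0) stop("zero denominator for ", metric)
  ci <- binom_ci(x, n, level, method)
  structure(list(metric = metric, point = x / n,
                 ci_low = ci[1], ci_high = ci[2],
                 level = level, x = x, n = n, method = method),
            class = "bnhl_accuracy")
}

#' Sensitivity and positive predictive value with exact intervals
#'
#' `sensitivity()` is TP/(TP+FN), the fraction of true cases captured;
#' `ppv()` is TP/(TP+FP), the fraction of included patients who are true
#' cases. Confidence intervals are Clopper-Pearson exact binomial by
#' default (the method that reproduces published validation intervals);
#' a Wilson score option is available.
#'
#' @param table a `bnhl_validation_table`.
#' @param level confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return An object of class `bnhl_accuracy` with `point`, `ci_low`,
#'   `ci_high`.
#' @export
sensitivity <- function(table, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(table, "bnhl_validation_table"))
  accuracy_estimate("sensitivity", table$tp, table$tp + table$fn, level,
                    match.arg(method))
}

#' @rdname sensitivity
#' @export
ppv <- function(table, level = 0.95,
                method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(table, "bnhl_validation_table"))
  accuracy_estimate("ppv", table$tp, table$tp + table$fp, level,
                    match.arg(method))
}

#' @export
print.bnhl_accuracy <- function(x, ...) {
  cat(sprintf("%s: %.1f%% (%.0f%% CI %.1f-%.1f%%) [%d/%d]\n",
              x$metric, 100 * x$point, 100 * x$level, 100 * x$ci_low,
              100 * x$ci_high, x$x, x$n))
  invisible(x)
}

#' Pearson chi-square comparison of two demographic distributions
#'
#' Tests homogeneity of category counts between a cohort and a reference
#' registry with Pearson's chi-square statistic (no continuity
#' correction). Categories named in `drop_categories` are removed before
#' testing (e.g. Other/Unknown race categories absent from the reference
#' comparison).
#'
#' @param counts an r x 2 matrix or data.frame of category counts
#'   (rows = categories, columns = sources), with rownames.
#' @param drop_categories optional character vector of row names to drop.
#' @return An object of class `bnhl_chisq`: list with `counts`, `chi2`,
#'   `df`, `p`, `expected`.
#' @export
chi_square <- function(counts, drop_categories = NULL) {
  m <- as.matrix(counts)
  if (!is.null(drop_categories))
    m <- m[!rownames(m) %in% drop_categories, , drop = FALSE]
  if (nrow(m) < 2L || ncol(m) != 2L)
    stop("counts must be an r x 2 table with r >= 2 after drops")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("expected cell count of zero; drop empty categories first")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(counts = m, chi2 = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = ct$expected),
            class = "bnhl_chisq")
}

#' @export
print.bnhl_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Demographic comparison against a reference registry table
#'
#' Builds the r x 2 contingency table for one demographic variable from
#' a cohort-versus-reference count table and applies [chi_square()].
#' Race comparisons drop the Other/Unknown categories (absent from the
#' registry comparison); age and gender use all categories. The shipped
#' reference table carries the cohort and registry category counts for
#' age bands, gender and race (patients aged 20-21 already excluded via
#' the registry's age cap).
#'
#' @param variable one of `"age_category"`, `"gender"`, `"race"`.
#' @param reference data.frame with columns `variable`, `category`,
#'   `cohort`, `reference`; defaults to the shipped table.
#' @return A `bnhl_chisq` object.
#' @export
demographic_comparison <- function(variable = c("age_category", "gender",
                                                "race"),
                                   reference = seer_reference()) {
  variable <- match.arg(variable)
  rows <- reference[reference$variable == variable, ]
  m <- as.matrix(rows[, c("cohort", "reference")])
  rownames(m) <- rows$category
  drop <- if (variable == "race") c("other", "unknown") else NULL
  chi_square(m, drop_categories = drop)
}

#' Shipped reference tables
#'
#' `seer_reference()` returns the demographic comparison table (cohort
#' versus cancer-registry category counts); `validation_counts()` returns
#' the single-centre validation contingency counts for both phenotype
#' steps as `bnhl_validation_table` objects.
#'
#' @return `seer_reference()`: data.frame; `validation_counts()`: named
#'   list of `bnhl_validation_table`.
#' @export
seer_reference <- function() {
  utils::read.csv(system.file("extdata", "seer_comparison.csv",
                              package = "bnhlphenotype"),
                  stringsAsFactors = FALSE)
}

#' @rdname seer_reference
#' @export
validation_counts <- function() {
  df <- utils::read.csv(system.file("extdata", "validation_counts.csv",
                                    package = "bnhlphenotype"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    validation_table(df$tp[i], df$fp[i], df$fn[i], stage = df$stage[i]))
  names(out) <- df$stage
  out
}
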