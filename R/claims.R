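#' Administrative claims tables
#'
#' A `bnhl_claims` object bundles the four relational tables the phenotype
#' operates on: patient demographics, inpatient admissions, per-admission
#' diagnosis codes, and dated pharmacy billing lines. Dates are held
#' internally as integer day indices (days since 1970-01-01); calendar
#' parsing happens only at the file boundary, because every rule in the
#' phenotype is plain day arithmetic (45-day review window, 60-day
#' lookback, +/- 2-day schedule tolerance).
#'
#' @param patients data.frame with columns `institution_id`, `patient_id`,
#'   `age_years`, `sex` (`"male"`/`"female"`), `race`
#'   (`"white"`/`"black"`/`"other"`/`"unknown"`).
#' @param admissions data.frame with columns `institution_id`, `patient_id`,
#'   `admit_date`, `discharge_date` (integer day indices).
#' @param diagnoses data.frame with columns `institution_id`, `patient_id`,
#'   `admit_date`, `code_system` (`"ICD9"`/`"ICD10"`), `code`.
#' @param bills data.frame with columns `institution_id`, `patient_id`,
#'   `bill_date` (integer day index), `agent` (canonical agent name).
#' @param validate logical; run invariant checks (default `TRUE`).
#' @return An object of class `bnhl_claims`.
#' @export
bnhl_claims <- function(patients, admissions, diagnoses, bills,
                        validate = TRUE) {
  x <- structure(
    list(
      patients   = as.data.frame(patients),
      admissions = as.data.frame(admissions),
      diagnoses  = as.data.frame(diagnoses),
      bills      = as.data.frame(bills)
    ),
    class = "bnhl_claims"
  )
  x$admissions <- x$admissions[order(x$admissions$institution_id,
                                     x$admissions$patient_id,
                                     x$admissions$admit_date,
                                     x$admissions$discharge_date), ,
                               drop = FALSE]
  rownames(x$admissions) <- NULL
  x$bills <- x$bills[order(x$bills$institution_id, x$bills$patient_id,
                           x$bills$bill_date, x$bills$agent), , drop = FALSE]
  rownames(x$bills) <- NULL
  x$diagnoses <- x$diagnoses[order(x$diagnoses$institution_id,
                                   x$diagnoses$patient_id,
                                   x$diagnoses$admit_date,
                                   x$diagnoses$code_system,
                                   x$diagnoses$code), , drop = FALSE]
  rownames(x$diagnoses) <- NULL
  x$patients <- x$patients[order(x$patients$institution_id,
                                 x$patients$patient_id), , drop = FALSE]
  rownames(x$patients) <- NULL
  if (validate) validate_claims(x)
  x
}

#' @export
print.bnhl_claims <- function(x, ...) {
  cat("<bnhl_claims>\n")
  cat(sprintf("  patients:   %d\n", nrow(x$patients)))
  cat(sprintf("  admissions: %d\n", nrow(x$admissions)))
  cat(sprintf("  diagnoses:  %d code rows\n", nrow(x$diagnoses)))
  cat(sprintf("  bills:      %d drug billing lines\n", nrow(x$bills)))
  invisible(x)
}

patient_key <- function(df) paste(df$institution_id, df$patient_id, sep = "\r")

validate_claims <- function(x) {
  key <- patient_key(x$patients)
  if (anyDuplicated(key))
    stop("duplicate (institution_id, patient_id) in patients table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  bad <- x$admissions$admit_date > x$admissions$discharge_date
  if (any(bad))
    stop(sprintf("admission with admit_date after discharge_date (row %d)",
                 which(bad)[1]))
  for (tab in c("admissions", "diagnoses", "bills")) {
    orphan <- !(patient_key(x[[tab]]) %in% key)
    if (any(orphan))
      stop(sprintf("%s row %d refers to a patient absent from the patients table",
                   tab, which(orphan)[1]))
  }
  # every drug bill must fall within one of the patient's admission spans
  adm <- split(x$admissions, patient_key(x$admissions))
  bk <- patient_key(x$bills)
  for (i in seq_len(nrow(x$bills))) {
    a <- adm[[bk[i]]]
    d <- x$bills$bill_date[i]
    if (is.null(a) || !any(d >= a$admit_date & d <= a$discharge_date))
      stop(sprintf(
        "bills row %d: bill_date %s for patient %s lies outside every admission span",
        i, format_day(d), x$bills$patient_id[i]))
  }
  invisible(x)
}

parse_day <- function(x, file, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(x) & nzchar(x)
  if (any(bad))
    stop(sprintf("%s: unparseable %s '%s' at data row %d (expected ISO-8601)",
                 file, col, x[which(bad)[1]], which(bad)[1]))
  as.integer(d)
}

format_day <- function(d) format(as.Date(d, origin = "1970-01-01"))

read_table_checked <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  df
}

#' Read a claims file set
#'
#' Reads `patients.csv`, `admissions.csv`, `diagnoses.csv` and `bills.csv`
#' from a directory (comma-delimited UTF-8, header row, ISO-8601 dates) and
#' assembles a validated [bnhl_claims] object. Grouping and sorting are
#' canonical, so the result is invariant to the row order of the input
#' files. Malformed rows are rejected with row-level diagnostics; a missing
#' column raises a schema error naming the column.
#'
#' @param dir directory containing the four CSV files.
#' @return A [bnhl_claims] object.
#' @export
read_claims <- function(dir) {
  if (!dir.exists(dir)) stop("claims directory not found: ", dir)
  p <- read_table_checked(file.path(dir, "patients.csv"),
    c("institution_id", "patient_id", "age_years", "sex", "race"))
  p$age_years <- as.integer(p$age_years)
  if (any(is.na(p$age_years) | p$age_years < 0))
    stop(sprintf("patients.csv: invalid age_years at data row %d",
                 which(is.na(p$age_years) | p$age_years < 0)[1]))
  bad_sex <- !p$sex %in% c("male", "female")
  if (any(bad_sex))
    stop(sprintf("patients.csv: invalid sex '%s' at data row %d",
                 p$sex[which(bad_sex)[1]], which(bad_sex)[1]))
  a <- read_table_checked(file.path(dir, "admissions.csv"),
    c("institution_id", "patient_id", "admit_date", "discharge_date"))
  a$admit_date     <- parse_day(a$admit_date, "admissions.csv", "admit_date")
  a$discharge_date <- parse_day(a$discharge_date, "admissions.csv",
                                "discharge_date")
  d <- read_table_checked(file.path(dir, "diagnoses.csv"),
    c("institution_id", "patient_id", "admit_date", "code_system", "code"))
  d$admit_date <- parse_day(d$admit_date, "diagnoses.csv", "admit_date")
  bad_sys <- !d$code_system %in% c("ICD9", "ICD10")
  if (any(bad_sys))
    stop(sprintf("diagnoses.csv: unknown code_system '%s' at data row %d",
                 d$code_system[which(bad_sys)[1]], which(bad_sys)[1]))
  b <- read_table_checked(file.path(dir, "bills.csv"),
    c("institution_id", "patient_id", "bill_date", "agent"))
  b$bill_date <- parse_day(b$bill_date, "bills.csv", "bill_date")
  bnhl_claims(p, a, d, b)
}

#' Write a claims file set
#'
#' Inverse of [read_claims()]: emits the four CSV files with ISO-8601 dates.
#'
#' @param claims a [bnhl_claims] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(claims, dir) {
  stopifnot(inherits(claims, "bnhl_claims"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- claims$patients
  a <- claims$admissions
  a$admit_date     <- format_day(a$admit_date)
  a$discharge_date <- format_day(a$discharge_date)
  d <- claims$diagnoses
  d$admit_date <- format_day(d$admit_date)
  b <- claims$bills
  b$bill_date <- format_day(b$bill_date)
  utils::write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(a, file.path(dir, "admissions.csv"), row.names = FALSE)
  utils::write.csv(d, file.path(dir, "diagnoses.csv"), row.names = FALSE)
  utils::write.csv(b, file.path(dir, "bills.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write and read cohort decisions
#'
#' `write_cohort()` serialises a decisions data.frame (one row per patient:
#' `institution_id`, `patient_id`, `included`, `rule`, `matched_cycles`) to
#' CSV; matched cycles are encoded as semicolon-separated `NAME@date`
#' entries in ascending date order. `read_cohort()` restores it losslessly.
#'
#' @param decisions data.frame of cohort decisions (see [bnhl_phenotype()]).
#' @param path output CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the decisions data.frame.
#' @export
write_cohort <- function(decisions, path) {
  cols <- c("institution_id", "patient_id", "included", "rule",
            "matched_cycles")
  missing <- setdiff(cols, names(decisions))
  if (length(missing))
    stop("decisions lack column(s): ", paste(missing, collapse = ", "))
  out <- decisions[, cols, drop = FALSE]
  out$included <- ifelse(out$included, "true", "false")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open output path: ", path))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read_table_checked(path, c("institution_id", "patient_id",
                                   "included", "rule", "matched_cycles"))
  df$included <- df$included == "true"
  df
}

# "COPADM@2004-03-01;COP@2004-02-08" -> canonical ascending-date encoding
encode_cycles <- function(matches) {
  if (is.null(matches) || length(matches) == 0L) return("")
  anchors <- vapply(matches, function(m) m$anchor_day, numeric(1))
  ord <- order(anchors)
  paste(vapply(matches[ord], function(m)
    paste0(m$template, "@", format_day(m$anchor_day)), character(1)),
    collapse = ";")
}
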