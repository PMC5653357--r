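write_raw_claims <- function(dir, patients, admissions, diagnoses, bills) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(patients, file.path(dir, "patients.csv"))
  writeLines(admissions, file.path(dir, "admissions.csv"))
  writeLines(diagnoses, file.path(dir, "diagnoses.csv"))
  writeLines(bills, file.path(dir, "bills.csv"))
  dir
}

hdr <- list(
  patients = "institution_id,patient_id,age_years,sex,race",
  admissions = "institution_id,patient_id,admit_date,discharge_date",
  diagnoses = "institution_id,patient_id,admit_date,code_system,code",
  bills = "institution_id,patient_id,bill_date,agent"
)

test_that("reader groups rows by patient, sorts admissions, and is invariant to row order", {
  adm_rows <- c("H1,P2,2010-03-01,2010-03-05",
                "H1,P1,2010-01-10,2010-01-15",
                "H1,P1,2010-01-01,2010-01-04")
  d1 <- write_raw_claims(
    file.path(tempdir(), "c1"),
    c(hdr$patients, "H1,P1,7,male,white", "H1,P2,12,female,black"),
    c(hdr$admissions, adm_rows),
    c(hdr$diagnoses, "H1,P1,2010-01-01,ICD9,200.20"),
    c(hdr$bills, "H1,P1,2010-01-02,vincristine"))
  cl <- read_claims(d1)
  expect_equal(nrow(cl$patients), 2L)
  expect_equal(nrow(cl$admissions), 3L)
  p1adm <- cl$admissions[cl$admissions$patient_id == "P1", ]
  expect_false(is.unsorted(p1adm$admit_date))
  # shuffled input rows give an identical object
  d2 <- write_raw_claims(
    file.path(tempdir(), "c2"),
    c(hdr$patients, "H1,P2,12,female,black", "H1,P1,7,male,white"),
    c(hdr$admissions, rev(adm_rows)),
    c(hdr$diagnoses, "H1,P1,2010-01-01,ICD9,200.20"),
    c(hdr$bills, "H1,P1,2010-01-02,vincristine"))
  expect_identical(read_claims(d1), read_claims(d2))
})

test_that("empty files with valid headers give an empty collection", {
  d <- write_raw_claims(file.path(tempdir(), "c_empty"),
                        hdr$patients, hdr$admissions, hdr$diagnoses,
                        hdr$bills)
  cl <- read_claims(d)
  expect_s3_class(cl, "bnhl_claims")
  expect_equal(nrow(cl$patients), 0L)
  expect_equal(nrow(cl$bills), 0L)
})

test_that("schema and row-level validation errors carry diagnostics", {
  base <- function(dir, bills_rows)
    write_raw_claims(dir,
                     c(hdr$patients, "H1,P1,7,male,white"),
                     c(hdr$admissions, "H1,P1,2010-01-01,2010-01-05"),
                     c(hdr$diagnoses, "H1,P1,2010-01-01,ICD9,200.20"),
                     bills_rows)
  # missing required column names the column
  d <- file.path(tempdir(), "c_schema")
  base(d, hdr$bills)
  writeLines(c("institution_id,patient_id,agent", "H1,P1,vincristine"),
             file.path(d, "bills.csv"))
  expect_error(read_claims(d), "bill_date")
  # unparseable date reports the row
  d <- base(file.path(tempdir(), "c_baddate"),
            c(hdr$bills, "H1,P1,01/02/2010,vincristine"))
  expect_error(read_claims(d), "row 1")
  # bill outside every admission span is a row-level validation error
  d <- base(file.path(tempdir(), "c_span"),
            c(hdr$bills, "H1,P1,2010-02-01,vincristine"))
  expect_error(read_claims(d), "outside every admission span")
})

test_that("cohort decisions round-trip losslessly through CSV", {
  dec <- data.frame(
    institution_id = rep("H1", 10),
    patient_id = sprintf("P%02d", 1:10),
    included = rep(c(TRUE, FALSE), 5),
    rule = rep(c("TWO_CYCLE_STANDARD", "EXCLUDED"), 5),
    matched_cycles = rep(c("COP@2010-01-01;COPADM@2010-01-22", ""), 5),
    stringsAsFactors = FALSE)
  path <- file.path(tempdir(), "cohort_rt.csv")
  write_cohort(dec, path)
  expect_identical(read_cohort(path), dec)
  # empty collection -> header-only file
  write_cohort(dec[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_cohort(path)), 0L)
})

test_that("matched cycles serialize in ascending date order", {
  mk <- function(name, day) list(template = name, anchor_day = day)
  enc <- bnhlphenotype:::encode_cycles(list(mk("COPADM", DAY0 + 21L),
                                            mk("COP", DAY0),
                                            mk("COPADM", DAY0 + 42L)))
  parts <- strsplit(enc, ";")[[1]]
  expect_equal(length(parts), 3L)
  dates <- as.Date(sub(".*@", "", parts))
  expect_false(is.unsorted(dates))
  expect_equal(sub("@.*", "", parts[1]), "COP")
})

test_that("claims invariants reject inconsistent tables", {
  adm <- data.frame(admit = DAY0, discharge = DAY0 + 5L)
  dx <- data.frame(admit = DAY0, sys = "ICD9", code = "200.20")
  expect_error(
    one_patient_claims(adm, dx, data.frame(day = DAY0 + 30L,
                                           agent = "vincristine")),
    "outside every admission span")
  expect_error(
    one_patient_claims(data.frame(admit = DAY0 + 5L, discharge = DAY0),
                       dx, data.frame(day = integer(0),
                                      agent = character(0))),
    "admit_date after discharge_date")
})
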