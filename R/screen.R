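#' Step 1: diagnosis-code screen
#'
#' Flags every patient carrying at least one diagnosis code whose prefix
#' matches the screening table (any admission, any code position), and
#' anchors the index admission at the earliest admission carrying a
#' qualifying code (ties broken by discharge date, then input order).
#'
#' @param claims a [bnhl_claims] object.
#' @param codes screening code table from [load_codes()].
#' @return data.frame with one row per patient: `institution_id`,
#'   `patient_id`, `passed_code_screen`, `index_admission_date` (integer
#'   day, `NA` for screen failures), `passed_billing_filter` (initialised
#'   `NA`, set by [billing_filter()]).
#' @export
screen_codes <- function(claims, codes = load_codes()) {
  stopifnot(inherits(claims, "bnhl_claims"))
  if (nrow(codes) == 0L) stop("screening code table is empty")
  dx <- claims$diagnoses
  hit <- rep(FALSE, nrow(dx))
  for (sys in unique(codes$code_system)) {
    prefixes <- codes$code_prefix[codes$code_system == sys]
    rows <- dx$code_system == sys
    if (!any(rows)) next
    m <- rep(FALSE, sum(rows))
    for (p in prefixes) m <- m | startsWith(dx$code[rows], p)
    hit[rows] <- m
  }
  qual <- dx[hit, , drop = FALSE]
  # earliest qualifying admission per patient; discharge-date tiebreak via
  # the canonical admission sort in bnhl_claims
  adm <- claims$admissions
  akey <- paste(patient_key(adm), adm$admit_date, sep = "\r")
  qkey <- paste(patient_key(qual), qual$admit_date, sep = "\r")
  qual_first <- tapply(qual$admit_date, patient_key(qual), min)
  p <- claims$patients
  key <- patient_key(p)
  idx <- unname(qual_first[key])
  data.frame(
    institution_id = p$institution_id,
    patient_id = p$patient_id,
    passed_code_screen = !is.na(idx),
    index_admission_date = as.integer(idx),
    passed_billing_filter = NA,
    stringsAsFactors = FALSE
  )
}

#' Step 1: chemotherapy-billing filter
#'
#' Among patients passing the code screen, excludes those lacking billing
#' data for all pre-specified screen agents: a single bill for any one
#' screen agent suffices to stay in.
#'
#' @param screen data.frame from [screen_codes()].
#' @param claims the same [bnhl_claims] object.
#' @param ontology a `bnhl_ontology`.
#' @return `screen` with `passed_billing_filter` filled in (`FALSE` for
#'   code-screen failures).
#' @export
billing_filter <- function(screen, claims, ontology = load_ontology()) {
  stopifnot(inherits(claims, "bnhl_claims"))
  b <- claims$bills
  agents <- if (nrow(b)) canonical_agent(b$agent, ontology) else character(0)
  has_screen_agent <- unique(patient_key(b)[agents %in%
                                              ontology$screen_agents])
  key <- patient_key(screen)
  screen$passed_billing_filter <-
    screen$passed_code_screen & key %in% has_screen_agent
  screen
}
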