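#' Specification for a synthetic claims cohort
#'
#' Describes the statistical structure of a simulated hospital cohort as
#' the phenotype assumes it: a mixture of true de novo B-NHL patients
#' (treated on standard regimens, with within-tolerance schedule
#' deviations), the false-positive mechanisms observed under
#' code-based screening (miscoded alternate diagnoses, relapsed disease
#' re-treated after an earlier era, late-course transfers-in, coding
#' without malignancy), and two planted false-negative mechanisms
#' (qualifying therapy without a screening code; regimens altered beyond
#' the matcher's tolerance).
#'
#' Default proportions follow the validation experience of code-based
#' screening: the false-positive mixture is 85.7% alternate diagnoses,
#' 1.4% relapsed, 10.0% transfer-in, 2.9% no malignancy; 9/106 of true
#' patients are planted false negatives split 5:4 between the missing
#' code and altered regimen mechanisms; 4/60 of alternate-diagnosis
#' patients are treated on true B-NHL regimens (and so survive
#' chemotherapy review as false positives), as is every relapsed
#' patient. Demographics default to the assembled-cohort category
#' frequencies (age bands, 75.8% male, race mix) and are sampled
#' independently of disease label.
#'
#' @param n_patients number of patients to simulate.
#' @param true_bnhl_fraction proportion of patients with true de novo
#'   B-NHL (default 0.6, matching the share of true cases among
#'   code-screen-positive patients in single-centre validation, 103/173).
#' @param fp_mixture named proportions over the four false-positive
#'   mechanisms; must sum to 1.
#' @param fn_fraction proportion of true patients planted as false
#'   negatives.
#' @param fn_mechanisms named proportions over the two false-negative
#'   mechanisms; must sum to 1.
#' @param alt_on_regimen_fraction proportion of alternate-diagnosis
#'   patients treated on a B-NHL regimen.
#' @param deviation list: `shift_days` (support of the per-class day
#'   shift, default 0:2), `class_drop_prob` (per-cycle probability of
#'   one absent class, default 0.1), `extra_steroid_mean` (Poisson mean
#'   of additional steroid days, default 2).
#' @param intercycle_gap_days canonical gap between consecutive cycle
#'   anchors (default 21).
#' @param regimen_weights named weights over the qualifying treatment
#'   plans.
#' @param demographics list of category probability vectors for
#'   `age_category`, `sex`, `race`.
#' @param seed integer seed; generation is fully reproducible.
#' @return A list of class `bnhl_cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        true_bnhl_fraction = 0.6,
                        fp_mixture = c(alternate_diagnosis = 0.857,
                                       relapsed = 0.014,
                                       transfer_in = 0.100,
                                       no_malignancy = 0.029),
                        fn_fraction = 9 / 106,
                        fn_mechanisms = c(missing_dx_code = 5 / 9,
                                          altered_regimen = 4 / 9),
                        alt_on_regimen_fraction = 4 / 60,
                        deviation = list(shift_days = 0:2,
                                         class_drop_prob = 0.1,
                                         extra_steroid_mean = 2),
                        intercycle_gap_days = 21L,
                        regimen_weights = c(cop_copadm = 0.25,
                                            cop_rcopadm = 0.25,
                                            two_copadm = 0.10,
                                            two_copad = 0.10,
                                            repoch = 0.15,
                                            bfm95 = 0.10,
                                            cop_only = 0.05),
                        demographics = list(
                          age_category = c(`<1` = 2, `1-4` = 182,
                                           `5-9` = 374, `10-14` = 434,
                                           `15-19` = 403) / 1395,
                          sex = c(male = 1058, female = 337) / 1395,
                          race = c(white = 951, black = 131, other = 294,
                                   unknown = 19) / 1395),
                        seed = 1L) {
  check_prop <- function(x, nm, names_needed = NULL) {
    if (any(x < 0 | x > 1) || abs(sum(x) - 1) > 1e-8)
      stop(nm, " must be proportions summing to 1")
    if (!is.null(names_needed) && !setequal(names(x), names_needed))
      stop(nm, " must be named: ", paste(names_needed, collapse = ", "))
  }
  check_prop(fp_mixture, "fp_mixture",
             c("alternate_diagnosis", "relapsed", "transfer_in",
               "no_malignancy"))
  check_prop(fn_mechanisms, "fn_mechanisms",
             c("missing_dx_code", "altered_regimen"))
  for (nm in names(demographics))
    check_prop(demographics[[nm]], paste0("demographics$", nm))
  stopifnot(n_patients >= 1,
            true_bnhl_fraction >= 0, true_bnhl_fraction <= 1,
            fn_fraction >= 0, fn_fraction <= 1,
            alt_on_regimen_fraction >= 0, alt_on_regimen_fraction <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 true_bnhl_fraction = true_bnhl_fraction,
                 fp_mixture = fp_mixture,
                 fn_fraction = fn_fraction,
                 fn_mechanisms = fn_mechanisms,
                 alt_on_regimen_fraction = alt_on_regimen_fraction,
                 deviation = deviation,
                 intercycle_gap_days = as.integer(intercycle_gap_days),
                 regimen_weights = regimen_weights / sum(regimen_weights),
                 demographics = demographics,
                 seed = as.integer(seed)),
            class = "bnhl_cohort_spec")
}

# day index of 2004-01-01, an arbitrary simulation epoch
.SIM_EPOCH <- 12419L

# sample one element without the scalar-x surprise of sample()
sample1 <- function(x) x[sample.int(length(x), 1L)]

# bills for one template cycle anchored at `anchor`; optional classes
# included with probability 0.5; deviations drawn from the deviation model
gen_cycle <- function(template, anchor, ontology, dev, deviate = TRUE) {
  cls <- template$classes
  keep <- !cls$optional | stats::runif(nrow(cls)) < 0.5
  cls <- cls[keep, , drop = FALSE]
  droppable <- which(!cls$optional & !cls$distinguishing &
                       sum(!cls$optional) > 1L)
  drop <- integer(0)
  if (deviate && length(droppable) &&
      stats::runif(1) < dev$class_drop_prob)
    drop <- sample1(droppable)
  day <- agent <- NULL
  for (i in seq_len(nrow(cls))) {
    if (i %in% drop) next
    shift <- if (deviate) sample1(dev$shift_days) else 0L
    cl <- cls$class[i]
    ag <- sample1(ontology$classes[[cl]])
    if (cl %in% ontology$steroid_classes) {
      extra <- if (deviate) stats::rpois(1L, dev$extra_steroid_mean) else 0L
      dd <- anchor + cls$offset[i] + seq(0L, template$cycle_span_days - 1L +
                                           extra)
    } else {
      dd <- anchor + cls$offset[i] + shift
    }
    day <- c(day, dd)
    agent <- c(agent, rep(ag, length(dd)))
  }
  data.frame(day = as.integer(day), agent = agent, stringsAsFactors = FALSE)
}

# anchors (relative to day 0) of the cycles in each qualifying plan
plan_cycles <- function(plan, gap) {
  switch(plan,
    cop_copadm  = list(c("COP", 0L), c("COPADM", gap)),
    cop_rcopadm = list(c("COP", 0L), c("RCOPADM", gap)),
    two_copadm  = list(c("COPADM", 0L), c("COPADM", gap)),
    two_copad   = list(c("COPAD", 0L), c("COPAD", gap)),
    repoch      = if (stats::runif(1) < 0.5)
                    list(c("COP", 0L), c("REPOCH", 14L), c("REPOCH", 35L))
                  else list(c("REPOCH", 0L), c("REPOCH", gap)),
    bfm95       = list(c("BFM95_C1", 0L), c("BFM95_C2", gap)),
    cop_only    = list(c("COP", 0L)),
    stop("unknown plan: ", plan))
}

#' Generate a labelled synthetic claims cohort
#'
#' Draws a cohort from a [cohort_spec()]: every patient receives a gold
#' label (one of `de_novo_bnhl`, `alternate_diagnosis`, `relapsed`,
#' `transfer_in`, `no_malignancy`), demographics, admissions with
#' diagnosis codes, and dated drug bills constructed per the label's
#' claims signature. Patients labelled `de_novo_bnhl` with
#' `intended_detectable = TRUE` are built to satisfy an inclusion rule
#' exactly (deviations strictly within tolerance); when `self_test` is
#' `TRUE` this contract is verified by running the matcher on each such
#' patient during generation.
#'
#' @param spec a [cohort_spec()].
#' @param ontology,templates,params phenotype configuration used for the
#'   claims signatures and the self-test.
#' @param self_test verify the detectability contract (default `TRUE`).
#' @return list with `claims` (a [bnhl_claims]) and `gold` (data.frame:
#'   `institution_id`, `patient_id`, `truth`, `intended_detectable`,
#'   `expected_included`).
#' @export
simulate_claims <- function(spec,
                            ontology = load_ontology(),
                            templates = load_templates(ontology = ontology),
                            params = phenotype_params(),
                            self_test = TRUE) {
  stopifnot(inherits(spec, "bnhl_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  dev <- spec$deviation
  gap <- spec$intercycle_gap_days
  labels <- sample(c("de_novo_bnhl", names(spec$fp_mixture)), n,
                   replace = TRUE,
                   prob = c(spec$true_bnhl_fraction,
                            (1 - spec$true_bnhl_fraction) * spec$fp_mixture))
  age_band <- sample(names(spec$demographics$age_category), n, replace = TRUE,
                     prob = spec$demographics$age_category)
  band_lo <- c(`<1` = 0L, `1-4` = 1L, `5-9` = 5L, `10-14` = 10L,
               `15-19` = 15L)
  band_hi <- c(`<1` = 0L, `1-4` = 4L, `5-9` = 9L, `10-14` = 14L,
               `15-19` = 19L)
  age <- band_lo[age_band] +
    floor(stats::runif(n) * (band_hi[age_band] - band_lo[age_band] + 1L))
  sex <- sample(names(spec$demographics$sex), n, replace = TRUE,
                prob = spec$demographics$sex)
  race <- sample(names(spec$demographics$race), n, replace = TRUE,
                 prob = spec$demographics$race)
  inst <- sprintf("H%02d", sample.int(8L, n, replace = TRUE))
  pid <- sprintf("P%05d", seq_len(n))
  icd9_codes <- c("200.00", "200.20", "200.50", "200.70", "200.80",
                  "202.80", "202.90")
  icd10_codes <- c("C83.30", "C83.70", "C85.10", "C85.90")
  adm_l <- dx_l <- bill_l <- vector("list", n)
  detectable <- rep(NA, n)
  expected <- logical(n)
  for (i in seq_len(n)) {
    index <- .SIM_EPOCH + sample.int(3650L, 1L)
    truth <- labels[i]
    use_icd10 <- stats::runif(1) < 0.25
    dxcode <- if (use_icd10) sample(icd10_codes, 1L)
              else sample(icd9_codes, 1L)
    dxsys <- if (use_icd10) "ICD10" else "ICD9"
    bills <- data.frame(day = integer(0), agent = character(0))
    has_code <- TRUE
    treat_plan <- NULL  # NULL = no qualifying therapy
    altered <- FALSE
    if (truth == "de_novo_bnhl") {
      fn <- stats::runif(1) < spec$fn_fraction
      if (fn) {
        mech <- sample(names(spec$fn_mechanisms), 1L,
                       prob = spec$fn_mechanisms)
        detectable[i] <- FALSE
        if (mech == "missing_dx_code") {
          treat_plan <- sample(names(spec$regimen_weights), 1L,
                               prob = spec$regimen_weights)
          has_code <- FALSE
        } else altered <- TRUE
      } else {
        detectable[i] <- TRUE
        expected[i] <- TRUE
        treat_plan <- sample(names(spec$regimen_weights), 1L,
                             prob = spec$regimen_weights)
      }
    } else if (truth == "alternate_diagnosis") {
      if (stats::runif(1) < spec$alt_on_regimen_fraction) {
        treat_plan <- sample(names(spec$regimen_weights), 1L,
                             prob = spec$regimen_weights)
        expected[i] <- TRUE
      }
    } else if (truth == "relapsed") {
      treat_plan <- sample(names(spec$regimen_weights), 1L,
                           prob = spec$regimen_weights)
      expected[i] <- TRUE
    }
    if (!is.null(treat_plan)) {
      for (cyc in plan_cycles(treat_plan, gap)) {
        anchor <- index + as.integer(cyc[2])
        bills <- rbind(bills, gen_cycle(templates[[cyc[1]]], anchor,
                                        ontology, dev))
      }
    } else if (altered) {
      # regimen reduced for comorbidity: two classes absent per cycle,
      # beyond the matcher's one-missing-class tolerance
      for (anchor in index + c(0L, gap)) {
        st <- sample(ontology$classes$steroid, 1L)
        bills <- rbind(bills, data.frame(
          day = anchor + c(0L, 0L, 0:4),
          agent = c("cyclophosphamide", "methotrexate", rep(st, 5L)),
          stringsAsFactors = FALSE))
      }
    } else if (truth == "alternate_diagnosis") {
      # Hodgkin-style ABVD: doxorubicin plus agents foreign to every
      # B-NHL template, so each candidate cycle is voided
      for (anchor in index + c(0L, 14L, 28L)) {
        bills <- rbind(bills, data.frame(
          day = rep(anchor, 4L),
          agent = c("doxorubicin", "bleomycin", "vinblastine",
                    "dacarbazine"),
          stringsAsFactors = FALSE))
      }
    } else if (truth == "transfer_in") {
      # continuation of therapy begun elsewhere: a lone late-course cycle
      bills <- gen_cycle(templates[["BFM95_C2"]], index, ontology, dev)
    }
    if (truth == "relapsed") {
      # prior-era treatment block, before the lookback horizon and
      # without a screening code on its admission
      pb <- gen_cycle(templates[["COPADM"]], index - 150L, ontology, dev)
      bills <- rbind(pb, bills)
    }
    # admissions: one per billing episode (>= 7-day gaps), anchored so
    # the first in-episode admission is the coded index admission
    if (nrow(bills)) {
      bills <- bills[order(bills$day), , drop = FALSE]
      days <- sort(unique(bills$day))
      epi <- cumsum(c(1L, diff(days) >= 7L))
      adm <- do.call(rbind, lapply(split(days, epi), function(d)
        data.frame(admit = min(d), discharge = max(d) + 1L)))
    } else {
      adm <- data.frame(admit = index, discharge = index + 3L)
    }
    # cop_only patients must have no inpatient encounter for 45 days
    # after the treatment discharge; everyone else returns for follow-up
    followup <- !(identical(treat_plan, "cop_only"))
    if (followup) {
      ret <- max(adm$discharge) + 50L + sample.int(30L, 1L)
      adm <- rbind(adm, data.frame(admit = ret, discharge = ret + 2L))
    }
    code_day <- adm$admit[which(adm$admit >= index)[1]]
    if (is.na(code_day)) code_day <- adm$admit[1]
    dx <- if (has_code)
      data.frame(admit = code_day, sys = dxsys, code = dxcode)
    else
      data.frame(admit = code_day, sys = "ICD9", code = "486")
    adm_l[[i]] <- cbind(i = i, adm)
    dx_l[[i]] <- cbind(i = i, dx)
    if (nrow(bills)) bill_l[[i]] <- cbind(i = i, bills)
    if (self_test && isTRUE(detectable[i])) {
      d <- decide_patient(bills, data.frame(admit_date = adm$admit,
                                            discharge_date = adm$discharge),
                          code_day, templates, ontology, params)
      if (!d$included)
        stop(sprintf(
          "detectability contract violated for patient %s (plan %s)",
          pid[i], treat_plan))
    }
  }
  A <- do.call(rbind, adm_l)
  D <- do.call(rbind, dx_l)
  B <- do.call(rbind, bill_l)
  claims <- bnhl_claims(
    patients = data.frame(institution_id = inst, patient_id = pid,
                          age_years = as.integer(age), sex = sex,
                          race = race, stringsAsFactors = FALSE),
    admissions = data.frame(institution_id = inst[A$i],
                            patient_id = pid[A$i],
                            admit_date = A$admit,
                            discharge_date = A$discharge,
                            stringsAsFactors = FALSE),
    diagnoses = data.frame(institution_id = inst[D$i],
                           patient_id = pid[D$i],
                           admit_date = D$admit,
                           code_system = D$sys, code = D$code,
                           stringsAsFactors = FALSE),
    bills = if (is.null(B)) data.frame(institution_id = character(0),
                                       patient_id = character(0),
                                       bill_date = integer(0),
                                       agent = character(0))
            else data.frame(institution_id = inst[B$i],
                            patient_id = pid[B$i],
                            bill_date = B$day, agent = B$agent,
                            stringsAsFactors = FALSE)
  )
  gold <- data.frame(institution_id = inst, patient_id = pid,
                     truth = labels, intended_detectable = detectable,
                     expected_included = expected,
                     stringsAsFactors = FALSE)
  gold <- gold[order(gold$institution_id, gold$patient_id), ]
  rownames(gold) <- NULL
  list(claims = claims, gold = gold)
}
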