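#' Matching and review parameters
#'
#' Tunable parameters of the step-2 chemotherapy review. Defaults encode
#' the phenotype's stated tolerances: intra-cycle schedule adjustments of
#' up to two days, absence of up to one chemotherapy class per cycle, a
#' 45-day review window from the index admission, a 60-day lookback for
#' patients first seen mid-protocol, and a 45-day no-return horizon for
#' the single-COP rule. The 7-day segmentation gap is a conservative
#' choice: intra-cycle spans are at most ~5 days and inter-cycle gaps at
#' least ~21, so any value in (5, 21) separates cycles identically.
#'
#' @param max_shift_days maximum deviation from a class's canonical day
#'   offset (days).
#' @param max_missing_classes maximum absent non-optional classes per
#'   cycle.
#' @param review_window_days review horizon after the index admission.
#' @param lookback_days lookback horizon before the index admission.
#' @param no_return_days encounter-free horizon after discharge required
#'   by the single-COP rule.
#' @param segmentation_gap_days chemotherapy-day gap that separates
#'   candidate cycles.
#' @return A list of class `bnhl_params`.
#' @export
phenotype_params <- function(max_shift_days = 2L,
                             max_missing_classes = 1L,
                             review_window_days = 45L,
                             lookback_days = 60L,
                             no_return_days = 45L,
                             segmentation_gap_days = 7L) {
  p <- list(max_shift_days = as.integer(max_shift_days),
            max_missing_classes = as.integer(max_missing_classes),
            review_window_days = as.integer(review_window_days),
            lookback_days = as.integer(lookback_days),
            no_return_days = as.integer(no_return_days),
            segmentation_gap_days = as.integer(segmentation_gap_days))
  stopifnot(all(vapply(p, function(x) !is.na(x) && x >= 0L, logical(1))))
  structure(p, class = "bnhl_params")
}

# annotate a (day, agent) bill frame with class and steroid-family flag
annotate_bills <- function(bills, ontology) {
  if (nrow(bills) == 0L)
    return(data.frame(day = integer(0), agent = character(0),
                      class = character(0), steroid = logical(0)))
  cmap <- agent_class_map(ontology)
  agent <- canonical_agent(bills$agent, ontology)
  cls <- unname(cmap[agent])
  out <- data.frame(day = as.integer(bills$day), agent = agent, class = cls,
                    steroid = !is.na(cls) & cls %in% ontology$steroid_classes,
                    stringsAsFactors = FALSE)
  # canonical order makes matching independent of billing-line input order
  out <- out[order(out$day, out$agent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment billing lines into candidate cycles
#'
#' Groups dated drug bills into candidate chemotherapy cycles: maximal
#' runs of chemotherapy days (days with at least one non-steroid bill)
#' in which consecutive chemotherapy days are separated by fewer than
#' `gap_days`. Steroid-only days never open a group and never bridge two
#' groups; steroid bills within four days of a group's span are attached
#' to it so the matcher can score the steroid class.
#'
#' @param bills data.frame with columns `day` (integer) and `agent` for
#'   one patient.
#' @param ontology a `bnhl_ontology`.
#' @param gap_days segmentation gap (default 7).
#' @return list of candidates, each a list with `start`, `end` (chemo-day
#'   span) and an annotated `bills` data.frame.
#' @export
segment_cycles <- function(bills, ontology = load_ontology(),
                           gap_days = 7L) {
  ab <- if (is.null(bills$class)) annotate_bills(bills, ontology) else bills
  chemo_days <- sort(unique(ab$day[!ab$steroid]))
  if (length(chemo_days) == 0L) return(list())
  grp <- cumsum(c(1L, diff(chemo_days) >= gap_days))
  lapply(split(chemo_days, grp), function(days) {
    s <- min(days); e <- max(days)
    keep <- (!ab$steroid & ab$day >= s & ab$day <= e) |
      (ab$steroid & ab$day >= s - 4L & ab$day <= e + 4L)
    list(start = s, end = e, bills = ab[keep, , drop = FALSE])
  })
}

#' Match a candidate cycle against a regimen template
#'
#' Searches anchor days for an alignment in which every non-optional
#' required class either has a bill within `max_shift` days of its
#' canonical offset or is among at most `max_missing` absent classes.
#' Steroid-family bills beyond the template days never penalise the
#' match; any non-template, non-steroid agent inside the candidate voids
#' it (a subset of a foreign regimen must not pass as a B-NHL cycle), and
#' a class marked `distinguishing` in the template may never be the
#' absent class (dropping doxorubicin from COPAD would collapse it into
#' COP, which carries different inclusion semantics).
#' Among feasible anchors the match minimising (number of missing
#' classes, maximum day shift) is reported, ties broken by the earliest
#' anchor.
#'
#' @param candidate one element of [segment_cycles()] output.
#' @param template one element of [load_templates()] output.
#' @param ontology a `bnhl_ontology`.
#' @param max_shift maximum day deviation (default 2).
#' @param max_missing maximum missing non-optional classes (default 1).
#' @return A list (`template`, `anchor_day`, `matched` data.frame with
#'   observed day and shift per class, `missing_classes`,
#'   `max_shift_days`, `extra_steroid_days`), or `NULL` if no alignment
#'   is feasible.
#' @export
match_cycle <- function(candidate, template, ontology = load_ontology(),
                        max_shift = 2L, max_missing = 1L) {
  ab <- candidate$bills
  if (nrow(ab) == 0L) return(NULL)
  tcls <- template$classes
  # voiding: non-steroid bills must all belong to template classes
  foreign <- !ab$steroid & (is.na(ab$class) | !ab$class %in% tcls$class)
  if (any(foreign)) return(NULL)
  span <- template$cycle_span_days
  days_by_class <- split(ab$day, ab$class)
  anchors <- seq(min(ab$day) - span + 1L, max(ab$day))
  best <- NULL
  for (a in anchors) {
    obs_day <- rep(NA_integer_, nrow(tcls))
    shift <- rep(NA_integer_, nrow(tcls))
    for (i in seq_len(nrow(tcls))) {
      dd <- days_by_class[[tcls$class[i]]]
      if (is.null(dd)) next
      dev <- abs(dd - a - tcls$offset[i])
      j <- which.min(dev)
      if (dev[j] <= max_shift) {
        obs_day[i] <- dd[j]
        shift[i] <- dev[j]
      }
    }
    missing <- tcls$class[is.na(obs_day) & !tcls$optional]
    if (length(missing) > max_missing) next
    # a distinguishing class may never be the absent one
    if (any(missing %in% tcls$class[tcls$distinguishing])) next
    ms <- if (all(is.na(shift))) 0L else max(shift, na.rm = TRUE)
    score <- c(length(missing), ms, a)
    if (is.null(best) || score[1] < best$score[1] ||
        (score[1] == best$score[1] && score[2] < best$score[2])) {
      matched <- !is.na(obs_day)
      best <- list(
        template = template$name,
        anchor_day = a,
        matched = data.frame(class = tcls$class[matched],
                             day = obs_day[matched],
                             shift = shift[matched],
                             stringsAsFactors = FALSE),
        missing_classes = missing,
        max_shift_days = ms,
        extra_steroid_days = length(setdiff(
          unique(ab$day[ab$steroid]), seq(a, a + span - 1L))),
        score = score
      )
    }
  }
  if (is.null(best)) return(NULL)
  best$score <- NULL
  best
}

# all (candidate, template) matches for a bill window
match_window <- function(bills, templates, ontology, params) {
  cands <- segment_cycles(bills, ontology, params$segmentation_gap_days)
  out <- list()
  for (ci in seq_along(cands)) {
    for (t in templates) {
      m <- match_cycle(cands[[ci]], t, ontology,
                       params$max_shift_days, params$max_missing_classes)
      if (!is.null(m)) {
        m$candidate <- ci
        out[[length(out) + 1L]] <- m
      }
    }
  }
  out
}

match_index <- function(matches) {
  if (length(matches) == 0L)
    return(data.frame(candidate = integer(0), template = character(0),
                      anchor = numeric(0)))
  data.frame(
    candidate = vapply(matches, `[[`, integer(1), "candidate"),
    template = vapply(matches, `[[`, character(1), "template"),
    anchor = vapply(matches, function(m) as.numeric(m$anchor_day),
                    numeric(1)),
    stringsAsFactors = FALSE
  )
}

# inclusion rules 1-4: qualifying multi-cycle patterns
apply_sequence_rules <- function(matches) {
  M <- match_index(matches)
  pick <- function(idx) matches[idx]
  # (1) a COPADM/RCOPADM plus a preceding COP or a second COPADM/RCOPADM
  core <- which(M$template %in% c("COPADM", "RCOPADM"))
  for (i in core) {
    partner <- which(
      (M$template %in% c("COPADM", "RCOPADM") & M$candidate != M$candidate[i]) |
        (M$template == "COP" & M$anchor < M$anchor[i] &
           M$candidate != M$candidate[i]))
    if (length(partner))
      return(list(rule = "TWO_CYCLE_STANDARD",
                  cycles = pick(c(partner[which.min(M$anchor[partner])], i))))
  }
  # (2) two COPAD courses
  copad <- which(M$template == "COPAD")
  if (length(unique(M$candidate[copad])) >= 2L) {
    first_per_cand <- copad[!duplicated(M$candidate[copad])]
    return(list(rule = "TWO_COPAD", cycles = pick(first_per_cand[1:2])))
  }
  # (3) at least two R-EPOCH cycles (with or without a preceding COP)
  rep_ <- which(M$template == "REPOCH")
  if (length(unique(M$candidate[rep_])) >= 2L) {
    first_per_cand <- rep_[!duplicated(M$candidate[rep_])]
    return(list(rule = "REPOCH_PAIR", cycles = pick(first_per_cand[1:2])))
  }
  # (4) BFM-95 course 1 followed by course 2
  c1 <- which(M$template == "BFM95_C1")
  c2 <- which(M$template == "BFM95_C2")
  for (i in c1) {
    j <- c2[M$anchor[c2] > M$anchor[i] & M$candidate[c2] != M$candidate[i]]
    if (length(j)) return(list(rule = "BFM95_SEQUENCE",
                               cycles = pick(c(i, j[1]))))
  }
  NULL
}

#' Decide cohort inclusion for one screened patient
#'
#' Applies the step-2 inclusion rules, in priority order, to the bills in
#' the review window `[index, index + review_window_days)`:
#' \enumerate{
#'   \item `TWO_CYCLE_STANDARD`: a COPADM or RCOPADM cycle plus either a
#'     preceding COP or a second COPADM/RCOPADM;
#'   \item `TWO_COPAD`: two COPAD courses;
#'   \item `REPOCH_PAIR`: at least two R-EPOCH cycles;
#'   \item `BFM95_SEQUENCE`: BFM-95 course 1 followed by course 2;
#'   \item `COP_ONLY_NO_RETURN`: at least one COP cycle and no inpatient
#'     encounter in the `no_return_days` after that admission's
#'     discharge (captures patients who do not survive to a second
#'     course);
#'   \item `LOOKBACK_RESCUE`: when only unpaired or later-course cycles
#'     (e.g. BFM-95 course 2) appear in-window, the review is extended
#'     `lookback_days` before the index admission and rules 1-4 are
#'     re-applied.
#' }
#' At most one rule is reported; priority affects only the label, since
#' inclusion is the disjunction of the rules.
#'
#' @param bills data.frame (`day`, `agent`) of the patient's drug bills.
#' @param admissions data.frame (`admit_date`, `discharge_date`) of the
#'   patient's admissions, integer days.
#' @param index_day index admission day from the code screen.
#' @param templates [load_templates()] output.
#' @param ontology a `bnhl_ontology`.
#' @param params [phenotype_params()].
#' @return list with `included`, `rule`, `matched_cycles` (list of
#'   [match_cycle()] results), `review_window` (start, end).
#' @export
decide_patient <- function(bills, admissions, index_day,
                           templates = load_templates(),
                           ontology = load_ontology(),
                           params = phenotype_params()) {
  if (is.na(index_day)) stop("decide_patient requires a screened patient")
  ab <- annotate_bills(bills, ontology)
  win <- c(index_day, index_day + params$review_window_days)
  inwin <- ab[ab$day >= win[1] & ab$day < win[2], , drop = FALSE]
  matches <- match_window(inwin, templates, ontology, params)
  hit <- apply_sequence_rules(matches)
  if (!is.null(hit))
    return(list(included = TRUE, rule = hit$rule,
                matched_cycles = hit$cycles, review_window = win))
  M <- match_index(matches)
  # (5) lone COP with no subsequent inpatient encounter
  cop <- which(M$template == "COP")
  if (length(cop)) {
    i <- cop[which.min(M$anchor[cop])]
    anchor <- M$anchor[i]
    cover <- which(admissions$admit_date <= anchor &
                     admissions$discharge_date >= anchor)
    if (length(cover) == 0L) {
      d0 <- matches[[i]]$matched$day[1]
      cover <- which(admissions$admit_date <= d0 &
                       admissions$discharge_date >= d0)
    }
    if (length(cover)) {
      disch <- max(admissions$discharge_date[cover])
      returned <- any(admissions$admit_date > disch &
                        admissions$admit_date <= disch + params$no_return_days)
      if (!returned)
        return(list(included = TRUE, rule = "COP_ONLY_NO_RETURN",
                    matched_cycles = matches[i], review_window = win))
    }
  }
  # (6) lookback: any in-window matched cycle that failed to qualify
  # suggests courses predating the index admission
  if (length(matches)) {
    ext <- c(index_day - params$lookback_days,
             index_day + params$review_window_days)
    extb <- ab[ab$day >= ext[1] & ab$day < ext[2], , drop = FALSE]
    ematches <- match_window(extb, templates, ontology, params)
    hit <- apply_sequence_rules(ematches)
    if (!is.null(hit))
      return(list(included = TRUE, rule = "LOOKBACK_RESCUE",
                  matched_cycles = hit$cycles, review_window = ext))
  }
  list(included = FALSE, rule = "EXCLUDED", matched_cycles = list(),
       review_window = win)
}

#' Inter-rater agreement between two decision sets
#'
#' Concordance is the fraction of identical include/exclude verdicts;
#' Cohen's kappa corrects it for chance agreement expected from the
#' marginal verdict frequencies, kappa = (p_o - p_e) / (1 - p_e). When
#' both raters use a single verdict category (p_e = 1), kappa is defined
#' as 1 for perfect agreement and 0 otherwise.
#'
#' @param decisions_a,decisions_b data.frames with `institution_id`,
#'   `patient_id`, `included` covering the same patients.
#' @return list with `concordance`, `kappa`, `n`.
#' @export
rate_agreement <- function(decisions_a, decisions_b) {
  ka <- patient_key(decisions_a)
  kb <- patient_key(decisions_b)
  if (length(ka) != length(kb) || !setequal(ka, kb) || anyDuplicated(ka))
    stop("decision sets must cover the same patients exactly once")
  b <- decisions_b$included[match(ka, kb)]
  a <- decisions_a$included
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  kappa <- if (pe >= 1) { if (po == 1) 1 else 0 } else (po - pe) / (1 - pe)
  list(concordance = po, kappa = kappa, n = length(a))
}
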