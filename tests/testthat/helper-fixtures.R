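# Shared configuration loaded once per test run
ONT <- load_ontology()
TPL <- load_templates(ontology = ONT)
DAY0 <- 15000L  # arbitrary integer day anchor

# Claims object for a single patient from plain day-indexed frames
one_patient_claims <- function(adm, dx, bills,
                               pid = "P1", inst = "H1",
                               age = 8L, sex = "male", race = "white") {
  bnhl_claims(
    patients = data.frame(institution_id = inst, patient_id = pid,
                          age_years = age, sex = sex, race = race),
    admissions = data.frame(institution_id = inst, patient_id = pid,
                            admit_date = adm$admit,
                            discharge_date = adm$discharge),
    diagnoses = data.frame(institution_id = inst, patient_id = pid,
                           admit_date = dx$admit, code_system = dx$sys,
                           code = dx$code),
    bills = if (nrow(bills))
      data.frame(institution_id = inst, patient_id = pid,
                 bill_date = bills$day, agent = bills$agent)
    else data.frame(institution_id = character(0),
                    patient_id = character(0), bill_date = integer(0),
                    agent = character(0))
  )
}

# Bills for one template cycle at its canonical offsets (no deviation)
canonical_cycle <- function(name, anchor, with_optional = FALSE) {
  t <- TPL[[name]]
  cls <- t$classes
  if (!with_optional) cls <- cls[!cls$optional, , drop = FALSE]
  agent_of <- function(cl) ONT$classes[[cl]][1]
  rows <- lapply(seq_len(nrow(cls)), function(i) {
    cl <- cls$class[i]
    if (cl %in% ONT$steroid_classes)
      data.frame(day = anchor + cls$offset[i] + 0:(t$cycle_span_days - 1L),
                 agent = agent_of(cl))
    else
      data.frame(day = anchor + cls$offset[i], agent = agent_of(cl))
  })
  do.call(rbind, rows)
}

# ---- independent oracles -------------------------------------------------

# exhaustive cycle segmentation under the stated gap rule
oracle_segment <- function(days_chemo, gap = 7L) {
  d <- sort(unique(days_chemo))
  if (!length(d)) return(list())
  groups <- list(d[1])
  for (x in d[-1]) {
    g <- groups[[length(groups)]]
    if (x - max(g) < gap) groups[[length(groups)]] <- c(g, x)
    else groups[[length(groups) + 1L]] <- x
  }
  groups
}

# brute force over anchors and explicit missing-class assignments;
# returns the minimal number of missing classes of any feasible
# alignment, or NULL if none
oracle_match <- function(candidate, template, ont = ONT,
                         max_shift = 2L, max_missing = 1L) {
  ab <- candidate$bills
  if (nrow(ab) == 0L) return(NULL)
  if (any(!ab$steroid &
            (is.na(ab$class) | !ab$class %in% template$classes$class)))
    return(NULL)
  req <- template$classes[!template$classes$optional, , drop = FALSE]
  miss_sets <- list(character(0))
  allowed <- req$class[!req$distinguishing]
  if (max_missing >= 1L)
    for (cl in allowed) miss_sets <- c(miss_sets, list(cl))
  if (max_missing >= 2L && length(allowed) >= 2L) {
    cmb <- utils::combn(allowed, 2L)
    for (j in seq_len(ncol(cmb))) miss_sets <- c(miss_sets, list(cmb[, j]))
  }
  anchors <- seq(min(ab$day) - template$cycle_span_days + 1L, max(ab$day))
  best <- Inf
  for (a in anchors) {
    for (ms in miss_sets) {
      ok <- TRUE
      for (i in seq_len(nrow(req))) {
        cl <- req$class[i]
        if (cl %in% ms) next
        dd <- ab$day[ab$class %in% cl]
        if (!length(dd) || min(abs(dd - a - req$offset[i])) > max_shift) {
          ok <- FALSE
          break
        }
      }
      if (ok) best <- min(best, length(ms))
    }
  }
  if (is.finite(best)) best else NULL
}

# closed-form Clopper-Pearson limits from the beta quantile function
oracle_cp <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

# Pearson statistic from first principles
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# random candidate cycles for matcher/oracle equivalence checks
random_candidate <- function(max_bills = 12L) {
  template_agents <- unique(unlist(ONT$classes))
  pool <- c(template_agents, "bleomycin")
  n <- sample.int(max_bills, 1L)
  bills <- data.frame(day = DAY0 + sample(0:9, n, replace = TRUE),
                      agent = sample(pool, n, replace = TRUE))
  segment_cycles(bills, ONT)
}
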