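cand_of <- function(bills) segment_cycles(bills, ONT)[[1]]

test_that("cycle segmentation splits on chemotherapy-day gaps only", {
  b <- data.frame(day = DAY0 + c(0:4, 21:25),
                  agent = "cyclophosphamide")
  expect_length(segment_cycles(b, ONT), 2L)
  expect_length(segment_cycles(data.frame(day = DAY0,
                                          agent = "vincristine"), ONT), 1L)
  # continuous daily steroid never bridges two cytotoxic blocks
  b2 <- rbind(data.frame(day = DAY0 + 0:30, agent = "prednisone"),
              data.frame(day = DAY0 + c(0:3, 21:24),
                         agent = "cyclophosphamide"))
  cands <- segment_cycles(b2, ONT)
  expect_length(cands, 2L)
  expect_equal(unname(vapply(cands, `[[`, integer(1), "start")),
               DAY0 + c(0L, 21L))
  # pure steroid exposure yields no candidates
  expect_length(segment_cycles(data.frame(day = DAY0 + 0:10,
                                          agent = "prednisone"), ONT), 0L)
  # oracle: exhaustive grouping under the gap rule on random day sets
  set.seed(3)
  for (rep in 1:40) {
    days <- DAY0 + sort(sample(0:60, sample(1:12, 1)))
    got <- segment_cycles(data.frame(day = days, agent = "etoposide"), ONT)
    want <- oracle_segment(days)
    expect_equal(length(got), length(want))
    expect_equal(lapply(got, function(g) sort(unique(g$bills$day))), want,
                 ignore_attr = TRUE)
  }
})

test_that("cycle matching honours the tolerance rules", {
  perfect <- cand_of(canonical_cycle("COPADM", DAY0))
  m <- match_cycle(perfect, TPL$COPADM, ONT)
  expect_equal(m$missing_classes, character(0))
  expect_equal(m$max_shift_days, 0L)
  expect_equal(m$anchor_day, DAY0)
  # doxorubicin far off its canonical day: no anchor can absorb the
  # deviation, so it is only feasible as the one permitted missing class
  b <- canonical_cycle("COPADM", DAY0)
  b$day[b$agent == "doxorubicin"] <- DAY0 + 6L  # canonical offset 1 -> +5
  m <- match_cycle(cand_of(b), TPL$COPADM, ONT)
  expect_equal(m$missing_classes, "doxorubicin")
  # two absent classes exceed tolerance
  b2 <- canonical_cycle("COPADM", DAY0)
  b2 <- b2[!b2$agent %in% c("doxorubicin", "methotrexate"), ]
  expect_null(match_cycle(cand_of(b2), TPL$COPADM, ONT))
  # a foreign cytotoxic agent voids the match
  b3 <- rbind(canonical_cycle("COPADM", DAY0),
              data.frame(day = DAY0 + 1L, agent = "bleomycin"))
  expect_null(match_cycle(cand_of(b3), TPL$COPADM, ONT))
  # additional steroid days never penalise
  b4 <- rbind(canonical_cycle("COPADM", DAY0),
              data.frame(day = DAY0 + 5:20, agent = "prednisolone"))
  m4 <- match_cycle(cand_of(b4), TPL$COPADM, ONT)
  expect_equal(m4$missing_classes, character(0))
  expect_gt(m4$extra_steroid_days, 0L)
  # a plain COP cycle must not pass as COPAD (doxorubicin distinguishes)
  cop <- cand_of(canonical_cycle("COP", DAY0))
  expect_null(match_cycle(cop, TPL$COPAD, ONT))
  expect_equal(match_cycle(cop, TPL$COP, ONT)$missing_classes,
               character(0))
})

test_that("matcher agrees with exhaustive anchor/missing-class search", {
  set.seed(29)
  n_checked <- 0L
  for (rep in 1:150) {
    cands <- random_candidate()
    tmpl <- TPL[[sample(names(TPL), 1L)]]
    for (cand in cands) {
      got <- match_cycle(cand, tmpl, ONT)
      want <- oracle_match(cand, tmpl, ONT)
      if (is.null(want)) expect_null(got)
      else {
        expect_false(is.null(got))
        expect_equal(length(got$missing_classes), want)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100L)
})

decide_case <- function(bills, index = DAY0, extra_adm = NULL) {
  days <- sort(unique(bills$day))
  epi <- cumsum(c(1L, diff(days) >= 7L))
  adm <- do.call(rbind, lapply(split(days, epi), function(d)
    data.frame(admit_date = min(d), discharge_date = max(d) + 1L)))
  if (!is.null(extra_adm)) adm <- rbind(adm, extra_adm)
  decide_patient(bills, adm, index, TPL, ONT, phenotype_params())
}

test_that("inclusion rules fire as specified", {
  # COP then COPADM
  d <- decide_case(rbind(canonical_cycle("COP", DAY0),
                         canonical_cycle("COPADM", DAY0 + 21L)))
  expect_true(d$included)
  expect_equal(d$rule, "TWO_CYCLE_STANDARD")
  # two COPAD courses
  d <- decide_case(rbind(canonical_cycle("COPAD", DAY0),
                         canonical_cycle("COPAD", DAY0 + 21L)))
  expect_true(d$included)
  # two R-EPOCH cycles
  d <- decide_case(rbind(canonical_cycle("REPOCH", DAY0),
                         canonical_cycle("REPOCH", DAY0 + 21L)))
  expect_true(d$included)
  expect_equal(d$rule, "REPOCH_PAIR")
  # BFM-95 course 1 then course 2
  d <- decide_case(rbind(canonical_cycle("BFM95_C1", DAY0),
                         canonical_cycle("BFM95_C2", DAY0 + 21L)))
  expect_true(d$included)
  expect_equal(d$rule, "BFM95_SEQUENCE")
  # a single COPADM with no partner cycle is insufficient
  d <- decide_case(canonical_cycle("COPADM", DAY0))
  expect_false(d$included)
  expect_equal(d$rule, "EXCLUDED")
  # two plain COP cycles are insufficient
  d <- decide_case(rbind(canonical_cycle("COP", DAY0),
                         canonical_cycle("COP", DAY0 + 21L)),
                   extra_adm = data.frame(admit_date = DAY0 + 50L,
                                          discharge_date = DAY0 + 52L))
  expect_false(d$included)
})

test_that("the lone-COP rule depends on the no-return condition", {
  cop <- canonical_cycle("COP", DAY0)
  # no subsequent inpatient encounter: included
  d <- decide_case(cop)
  expect_true(d$included)
  expect_equal(d$rule, "COP_ONLY_NO_RETURN")
  # re-admitted 10 days after discharge: excluded
  d <- decide_case(cop, extra_adm = data.frame(admit_date = DAY0 + 15L,
                                               discharge_date = DAY0 + 18L))
  expect_false(d$included)
})

test_that("the 60-day lookback rescues patients first coded mid-protocol", {
  bills <- rbind(canonical_cycle("COPADM", DAY0 - 40L),
                 canonical_cycle("COPADM", DAY0 + 2L))
  d <- decide_case(bills, index = DAY0)
  expect_true(d$included)
  expect_equal(d$rule, "LOOKBACK_RESCUE")
  expect_equal(d$review_window[1], DAY0 - 60L)
  # a cycle beyond the lookback horizon does not rescue
  far <- rbind(canonical_cycle("COPADM", DAY0 - 100L),
               canonical_cycle("COPADM", DAY0 + 2L))
  d2 <- decide_case(far, index = DAY0)
  expect_false(d2$included)
  # a lone late-course cycle with an empty lookback stays excluded
  d3 <- decide_case(canonical_cycle("BFM95_C2", DAY0), index = DAY0)
  expect_false(d3$included)
})

test_that("decisions are deterministic and invariant to billing-line order", {
  set.seed(41)
  for (rep in 1:10) {
    spec_bills <- rbind(canonical_cycle("COP", DAY0),
                        canonical_cycle("RCOPADM", DAY0 + 21L))
    shuf <- spec_bills[sample(nrow(spec_bills)), ]
    expect_identical(decide_case(spec_bills), decide_case(shuf))
  }
  expect_error(decide_patient(canonical_cycle("COP", DAY0),
                              data.frame(admit_date = DAY0,
                                         discharge_date = DAY0 + 6L),
                              NA_integer_),
               "screened")
})

test_that("loosening tolerances never excludes a previously included patient", {
  set.seed(57)
  for (rep in 1:30) {
    # a random two-cycle patient with haphazard deviations
    nm <- sample(c("COPADM", "RCOPADM", "COPAD", "REPOCH"), 1)
    b1 <- canonical_cycle(nm, DAY0)
    b2 <- canonical_cycle(nm, DAY0 + 21L)
    b2$day <- b2$day + sample(0:4, nrow(b2), replace = TRUE)
    drop_row <- sample(nrow(b1), sample(0:2, 1))
    if (length(drop_row)) b1 <- b1[-drop_row, ]
    bills <- rbind(b1, b2)
    base <- decide_case(bills)
    for (shift in 2:4) for (miss in 1:2) {
      days <- sort(unique(bills$day))
      epi <- cumsum(c(1L, diff(days) >= 7L))
      adm <- do.call(rbind, lapply(split(days, epi), function(d)
        data.frame(admit_date = min(d), discharge_date = max(d) + 1L)))
      loose <- decide_patient(bills, adm, DAY0, TPL, ONT,
                              phenotype_params(max_shift_days = shift,
                                               max_missing_classes = miss))
      if (base$included) expect_true(loose$included)
    }
  }
})

test_that("inter-rater agreement statistics behave as defined", {
  dec <- function(inc) data.frame(institution_id = "H1",
                                  patient_id = sprintf("P%03d",
                                                       seq_along(inc)),
                                  included = inc)
  a <- dec(rep(c(TRUE, FALSE), 50))
  ra <- rate_agreement(a, a)
  expect_equal(ra$concordance, 1)
  expect_equal(ra$kappa, 1)
  # one disagreement among 100 with balanced marginals
  b <- a
  b$included[1] <- FALSE
  expect_equal(rate_agreement(a, b)$concordance, 0.99)
  # independent verdicts at matched marginals give kappa near zero
  set.seed(91)
  k <- replicate(200, {
    x <- dec(sample(c(TRUE, FALSE), 50, replace = TRUE))
    y <- dec(sample(c(TRUE, FALSE), 50, replace = TRUE))
    rate_agreement(x, y)$kappa
  })
  expect_lt(abs(mean(k)), 0.05)
  # mismatched patient sets are rejected
  expect_error(rate_agreement(a, dec(rep(TRUE, 99))), "same patients")
  # cross-check kappa against an independent implementation
  if (requireNamespace("e1071", quietly = TRUE)) {
    x <- dec(sample(c(TRUE, FALSE), 80, replace = TRUE))
    y <- dec(sample(c(TRUE, FALSE), 80, replace = TRUE))
    tab <- table(x$included, y$included)
    expect_equal(rate_agreement(x, y)$kappa,
                 e1071::classAgreement(tab)$kappa)
  }
})
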