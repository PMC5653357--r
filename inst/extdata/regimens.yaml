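# B-NHL regimen cycle templates.
#
# Offsets are canonical day positions within the cycle (day 0 = first
# administered agent); the matcher's +/- 2-day tolerance absorbs schedule
# detail, so only the relative layout matters. Compositions:
#   COP      = cyclophosphamide + vincristine + steroid
#   COPADM   = COP + doxorubicin + methotrexate
#   RCOPADM  = COPADM + rituximab
#   COPAD    = COPADM - methotrexate
#   REPOCH   = rituximab + etoposide + vincristine + cyclophosphamide +
#              doxorubicin + steroid
#   BFM95_C1 = methotrexate + cytarabine + etoposide + ifosfamide +
#              dexamethasone (+/- vincristine)
#   BFM95_C2 = cyclophosphamide + doxorubicin + methotrexate +
#              dexamethasone (+/- vincristine)
templates:
  COP:
    cycle_span_days: 5
    classes:
      - {class: cyclophosphamide, offset: 0}
      - {class: vincristine, offset: 0}
      - {class: steroid, offset: 0}
  COPADM:
    cycle_span_days: 5
    classes:
      - {class: vincristine, offset: 0}
      - {class: methotrexate, offset: 0}
      - {class: steroid, offset: 0}
      - {class: cyclophosphamide, offset: 1}
      - {class: doxorubicin, offset: 1}
  RCOPADM:
    cycle_span_days: 5
    classes:
      - {class: rituximab, offset: 0}
      - {class: vincristine, offset: 0}
      - {class: methotrexate, offset: 0}
      - {class: steroid, offset: 0}
      - {class: cyclophosphamide, offset: 1}
      - {class: doxorubicin, offset: 1}
  COPAD:
    cycle_span_days: 5
    classes:
      - {class: cyclophosphamide, offset: 0}
      - {class: vincristine, offset: 0}
      # distinguishing: may never be the one absent class, else a plain
      # COP cycle would pass as a COPAD course
      - {class: doxorubicin, offset: 0, distinguishing: true}
      - {class: steroid, offset: 0}
  REPOCH:
    cycle_span_days: 5
    classes:
      - {class: rituximab, offset: 0}
      - {class: etoposide, offset: 0}
      - {class: vincristine, offset: 0}
      - {class: doxorubicin, offset: 0}
      - {class: steroid, offset: 0}
      - {class: cyclophosphamide, offset: 4}
  BFM95_C1:
    cycle_span_days: 5
    classes:
      - {class: dexamethasone, offset: 0}
      - {class: methotrexate, offset: 0}
      - {class: ifosfamide, offset: 0}
      - {class: cytarabine, offset: 3}
      - {class: etoposide, offset: 4}
      - {class: vincristine, offset: 0, optional: true}
  BFM95_C2:
    cycle_span_days: 5
    classes:
      - {class: dexamethasone, offset: 0}
      - {class: methotrexate, offset: 0}
      - {class: cyclophosphamide, offset: 1}
      - {class: doxorubicin, offset: 4}
      - {class: vincristine, offset: 0, optional: true}
# templates that typically appear later in cooperative-group protocols:
# finding one in the review window triggers the 60-day lookback
later_course_templates: [BFM95_C2]
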