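# Chemotherapy agent ontology for the B-NHL phenotype.
#
# `screen_agents` is the pre-specified agent list for the step-1 billing
# filter: a screened patient is excluded only if they lack billing for ALL
# of these agents. `agents` may list additional agents (decoy regimens in
# synthetic data, non-B-NHL protocols) that carry no class and therefore
# void a template match when they appear inside a candidate cycle.
agents:
  - cyclophosphamide
  - vincristine
  - doxorubicin
  - methotrexate
  - prednisone
  - prednisolone
  - methylprednisolone
  - rituximab
  - etoposide
  - ifosfamide
  - cytarabine
  - dexamethasone
  - bleomycin
  - vinblastine
  - dacarbazine
  - nelarabine
  - pegaspargase
classes:
  cyclophosphamide: [cyclophosphamide]
  vincristine: [vincristine]
  doxorubicin: [doxorubicin]
  methotrexate: [methotrexate]
  steroid: [prednisone, prednisolone, methylprednisolone]
  dexamethasone: [dexamethasone]
  rituximab: [rituximab]
  etoposide: [etoposide]
  ifosfamide: [ifosfamide]
  cytarabine: [cytarabine]
# classes whose members are corticosteroids: extra exposure never penalizes
# a match and steroid-only days never open or bridge a candidate cycle
steroid_classes: [steroid, dexamethasone]
screen_agents:
  - cyclophosphamide
  - vincristine
  - doxorubicin
  - methotrexate
  - prednisone
  - prednisolone
  - methylprednisolone
  - rituximab
  - etoposide
  - ifosfamide
  - cytarabine
  - dexamethasone
# billing-dialect synonyms, canonicalised case-insensitively
synonyms:
  cytoxan: cyclophosphamide
  oncovin: vincristine
  adriamycin: doxorubicin
  solu-medrol: methylprednisolone
  ara-c: cytarabine
  mesnex-ifosfamide: ifosfamide
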