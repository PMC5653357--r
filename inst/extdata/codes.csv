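code_system,code_prefix,description
ICD9,200.0,Reticulosarcoma
ICD9,200.2,Burkitt's leukemia or lymphoma
ICD9,200.5,Primary CNS lymphoma
ICD9,200.7,Large cell lymphoma
ICD9,200.8,Other named variants of reticulosarcoma and lymphosarcoma
ICD9,202.8,Other malignant lymphomas
ICD9,202.9,Other and unspecified malignant neoplasms of lymphoid and histiocytic tissue
ICD10,C83.3,Diffuse large B cell lymphoma
ICD10,C83.7,Burkitt's lymphoma
ICD10,C83.8,Other non-follicular lymphoma
ICD10,C83.9,Non-follicular (diffuse) lymphoma
ICD10,C85.1,Unspecified B cell lymphoma
ICD10,C85.2,Mediastinal (thymic) B cell lymphoma
ICD10,C85.8,Other specified types of non-Hodgkin lymphoma
ICD10,C85.9,"Non-Hodgkin lymphoma, unspecified"
ICD10,C96.9,"Malignant neoplasm of lymphoid, hematopoietic, and related tissue, unspecified"
ICD10,C96.Z,"Other specified malignant neoplasms of lymphoid, hematopoietic, and related tissue"
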