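{
  "variables": [
    {
      "name": "cohort",
      "states": ["PBC", "CBC"],
      "group": "selection"
    },
    {
      "name": "age35",
      "states": ["Yes", "No"],
      "group": "prognostic"
    },
    {
      "name": "histology",
      "states": ["Ductal and lobular neoplasm", "Epithelial neoplasms, NOS", "Adenocarcinomas", "Neoplasms, NOS", "Other histologies"],
      "group": "prognostic"
    },
    {
      "name": "grade",
      "states": ["Grade 1", "Grade 2", "Grade 3"],
      "group": "prognostic"
    },
    {
      "name": "vascular",
      "states": ["Yes", "No"],
      "group": "prognostic"
    },
    {
      "name": "ki67",
      "states": ["Yes", "No"],
      "group": "prognostic"
    },
    {
      "name": "receptors",
      "states": ["Luminal", "Luminal A", "Luminal B", "Luminal HER2", "HER2-enriched", "triple-negative"],
      "group": "prognostic"
    },
    {
      "name": "pT",
      "states": ["pT1", "pT2", "pT3", "pT4"],
      "group": "prognostic"
    },
    {
      "name": "pN",
      "states": ["pN0", "pN+"],
      "group": "prognostic"
    },
    {
      "name": "death_in_5y",
      "states": ["Yes", "No"],
      "group": "prognosis"
    },
    {
      "name": "chemo_neo",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "radio_neo",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "target_neo",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "hormon_neo",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "surgery",
      "states": ["Conservative", "Radical"],
      "group": "treatment"
    },
    {
      "name": "chemo_adju",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "radio_adju",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "target_adju",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "hormons_adiu",
      "states": ["Yes", "No"],
      "group": "treatment"
    },
    {
      "name": "dyslipidemia",
      "states": ["Pre", "Post", "No"],
      "group": "risk_factor"
    },
    {
      "name": "hypertension",
      "states": ["Pre", "Post", "No"],
      "group": "risk_factor"
    },
    {
      "name": "t2db",
      "states": ["Pre", "Post", "No"],
      "group": "risk_factor"
    },
    {
      "name": "cardiotoxicity",
      "states": ["Yes", "No"],
      "group": "target"
    },
    {
      "name": "ischemic_heart_disease",
      "states": ["Yes", "No"],
      "group": "target"
    },
    {
      "name": "cvds",
      "states": ["Yes", "No"],
      "group": "target"
    }
  ]
}
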