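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
      "name": "grade",
      "states": ["Grade 1", "Grade 2", "Grade 3"],
      "group": "prognostic"
    },
    {
      "name": "chemo_neo",
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
      "name": "hypertension",
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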