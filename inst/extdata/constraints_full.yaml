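context_node: cohort
tiers:
- - cohort
- - age35
  - histology
  - grade
  - vascular
  - ki67
  - receptors
  - pT
  - pN
- - chemo_neo
  - radio_neo
  - target_neo
  - hormon_neo
- - surgery
- - chemo_adju
  - radio_adju
  - target_adju
  - hormons_adiu
- - dyslipidemia
  - hypertension
  - t2db
  - cardiotoxicity
  - ischemic_heart_disease
- - cvds
  - death_in_5y
required:
- from: cohort
  to: age35
- from: cohort
  to: histology
- from: cohort
  to: grade
- from: cohort
  to: vascular
- from: cohort
  to: ki67
- from: cohort
  to: receptors
- from: cohort
  to: pT
- from: cohort
  to: pN
- from: grade
  to: chemo_neo
- from: receptors
  to: chemo_neo
- from: pT
  to: chemo_neo
- from: age35
  to: chemo_neo
- from: pT
  to: radio_neo
- from: receptors
  to: target_neo
- from: receptors
  to: hormon_neo
- from: age35
  to: hormon_neo
- from: chemo_neo
  to: surgery
- from: pT
  to: surgery
- from: surgery
  to: chemo_adju
- from: grade
  to: chemo_adju
- from: surgery
  to: radio_adju
- from: target_neo
  to: target_adju
- from: surgery
  to: target_adju
- from: hormon_neo
  to: hormons_adiu
- from: receptors
  to: hormons_adiu
- from: cohort
  to: hypertension
- from: hormons_adiu
  to: hypertension
- from: chemo_adju
  to: hypertension
- from: cohort
  to: dyslipidemia
- from: hormons_adiu
  to: dyslipidemia
- from: cohort
  to: t2db
- from: chemo_neo
  to: cardiotoxicity
- from: chemo_adju
  to: cardiotoxicity
- from: radio_adju
  to: cardiotoxicity
- from: target_adju
  to: cardiotoxicity
- from: hormons_adiu
  to: ischemic_heart_disease
- from: hypertension
  to: ischemic_heart_disease
- from: dyslipidemia
  to: ischemic_heart_disease
- from: t2db
  to: ischemic_heart_disease
- from: cardiotoxicity
  to: cvds
- from: ischemic_heart_disease
  to: cvds
- from: grade
  to: death_in_5y
- from: pT
  to: death_in_5y
- from: pN
  to: death_in_5y
forbidden: []
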