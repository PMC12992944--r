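name: department
factors:
- factor: age_40
  field: age
  op: ge
  cutoff: 40.0
  points: 1
  stage: pre_operative
- factor: bmi_25_30
  field: bmi
  op: band
  cutoff: 25.0
  cutoff2: 30.0
  points: 1
  stage: pre_operative
- factor: bmi_30
  field: bmi
  op: ge
  cutoff: 30.0
  points: 2
  stage: pre_operative
- factor: parity_3
  field: parity
  op: ge
  cutoff: 3.0
  points: 1
  stage: pre_operative
- factor: pre_eclampsia
  field: pre_eclampsia
  op: flag
  points: 1
  stage: pre_operative
- factor: multiple_pregnancy
  field: multiple_pregnancy
  op: flag
  points: 1
  stage: pre_operative
- factor: preterm
  field: gestational_age_at_delivery
  op: lt
  cutoff: 34.0
  points: 1
  stage: pre_operative
- factor: prolonged_labor
  field: prolonged_labor_gt24h
  op: flag
  points: 1
  stage: pre_operative
- factor: stillbirth
  field: stillbirth
  op: flag
  points: 1
  stage: pre_operative
- factor: medical_comorbidity
  field: medical_comorbidity
  op: flag
  points: 1
  stage: pre_operative
- factor: low_risk_thrombophilia
  field: low_risk_thrombophilia
  op: flag
  points: 1
  stage: pre_operative
- factor: current_smoker
  field: current_smoker
  op: flag
  points: 1
  stage: pre_operative
- factor: gross_varicose_veins
  field: gross_varicose_veins
  op: flag
  points: 1
  stage: pre_operative
- factor: current_systemic_infection
  field: current_systemic_infection
  op: flag
  points: 1
  stage: pre_operative
- factor: immobility
  field: immobility
  op: flag
  points: 1
  stage: pre_operative
- factor: family_history_vte
  field: family_history_vte
  op: flag
  points: 1
  stage: pre_operative
- factor: pph_or_transfusion
  field: pph_ml
  op: pph
  cutoff: 1000.0
  points: 1
  stage: post_operative_markup
thresholds:
  mechanical: 2.0
  pharmacologic: 3.0
dosing:
  weight_cutoff_kg: 100.0
  dose_low_mg: 40.0
  dose_high_mg: 60.0
  duration_days: 10.0
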