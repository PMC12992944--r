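name: ACCP-style
mechanical_policy: universal
type: accp
cutoffs:
  age: 35.0
  bmi: 30.0
  parity: 3.0
  preterm: 37.0
  pph: 1000.0
major:
- prior_vte_or_high_risk_thrombophilia
- immobility
- pre_eclampsia
minor:
- multiple_pregnancy
- prolonged_labor_gt24h
- stillbirth
- medical_comorbidity
- low_risk_thrombophilia
- current_smoker
- gross_varicose_veins
- current_systemic_infection
- family_history_vte
- age_35
- bmi_30
- parity_3
- preterm
- pph_or_transfusion
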