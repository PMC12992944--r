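name: RCOG-style
mechanical_policy: universal
type: rcog
cutoffs:
  age: 35.0
  bmi: 30.0
  parity: 3.0
  preterm: 37.0
  pph: 1000.0
factors:
- pre_eclampsia
- multiple_pregnancy
- prolonged_labor_gt24h
- stillbirth
- medical_comorbidity
- low_risk_thrombophilia
- current_smoker
- gross_varicose_veins
- current_systemic_infection
- immobility
- family_history_vte
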