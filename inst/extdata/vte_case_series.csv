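period,case_id,age,bmi,weight,parity,gestational_age_at_delivery,cs_urgency,pre_eclampsia,multiple_pregnancy,prolonged_labor_gt24h,stillbirth,medical_comorbidity,low_risk_thrombophilia,current_smoker,gross_varicose_veins,current_systemic_infection,immobility,family_history_vte,pph_ml,transfusion,on_antenatal_lmwh,prior_vte_or_high_risk_thrombophilia,reported_score,event_type
preprotocol,1,29,30,78,1,39,elective,0,0,0,0,0,0,0,0,0,0,0,300,0,0,0,2,pe
preprotocol,2,31,27,68,0,29.5,emergency,0,0,0,0,0,0,0,0,0,0,0,1000,0,0,0,3,pe
preprotocol,3,43,24,60,2,39,elective,0,0,0,0,0,0,0,0,0,0,0,1100,0,0,0,2,pe
preprotocol,4,26,23,58,2,39,elective,0,0,0,0,0,0,0,0,0,0,0,300,0,0,0,0,dvt
preprotocol,5,40,23,57,1,39,elective,0,0,0,0,1,0,0,0,0,0,0,300,0,0,0,2,dvt
preprotocol,6,45,31,80,1,39,elective,0,0,0,0,0,0,0,0,0,0,0,300,0,0,0,3,dvt
preprotocol,7,42,30,76,0,39,elective,0,0,0,0,0,0,0,0,0,0,0,400,0,0,0,3,dvt
preprotocol,8,46,23,60,0,36,emergency,1,1,0,0,0,0,0,0,0,0,0,500,0,0,0,3,pe
preprotocol,9,27,23,55,0,39,elective,0,0,0,0,1,0,0,0,0,0,0,300,0,0,0,1,dvt
preprotocol,10,38,28,70,0,39,elective,1,0,0,0,0,0,0,0,0,0,0,1200,0,0,0,3,dvt
preprotocol,11,38,27,66,1,39,elective,0,0,0,0,0,0,0,0,0,0,0,300,0,0,0,1,dvt
protocol,1,29,27,65,0,40,emergency,1,0,0,0,0,0,0,0,0,0,0,400,0,0,0,2,pe
protocol,2,39,29,72,0,31,emergency,1,0,0,1,0,0,0,0,0,0,0,500,0,0,0,4,pe
protocol,3,39,31,78,1,33,emergency,0,0,0,0,0,0,0,0,0,0,0,3000,0,0,0,4,pe
protocol,4,40,29,70,1,39,elective,0,0,0,0,0,0,0,0,0,0,0,1000,0,0,0,3,pe
protocol,5,40,28,70,1,38,emergency,0,0,0,0,0,0,0,0,0,0,0,400,0,0,0,1,dvt
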