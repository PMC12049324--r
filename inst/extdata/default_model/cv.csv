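item,category,value
reference_risk_10yr,,0.109
hazard_ratio,LOW,1.00
hazard_ratio,MODERATE,1.52
hazard_ratio,HIGH,2.04
hazard_ratio,VERY_HIGH,3.69
hazard_ratio,ESKD,12.00
event_proportion,myocardial_infarction,0.09
event_proportion,stroke_ischemic,0.63
event_proportion,stroke_ich,0.15
event_proportion,stroke_sah,0.06
event_proportion,other_cv_event,0.07
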