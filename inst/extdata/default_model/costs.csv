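category,yen
acei_arb,4015.00
sglt2i,96725.00
dialysis,5456714.14
gp_consultation,730.00
gp_tests_low,2870.00
gp_tests_moderate,480.00
gp_tests_high,960.00
gp_tests_very_high,0.00
gp_prescription_low,0.00
gp_prescription_moderate,3180.00
gp_prescription_high,0.00
gp_prescription_very_high,0.00
nephrologist_consultation,740.00
nephrologist_tests_low,0.00
nephrologist_tests_moderate,5370.00
nephrologist_tests_high,11460.00
nephrologist_tests_very_high,12670.00
nephrologist_prescription_low,0.00
nephrologist_prescription_moderate,0.00
nephrologist_prescription_high,30680.00
nephrologist_prescription_very_high,24740.00
other_nephrologist_low,0.00
other_nephrologist_moderate,2000.00
other_nephrologist_high,2000.00
other_nephrologist_very_high,10000.00
egfr_test,110.00
uacr_test,1730.00
upcr_test,810.00
vascular_access_surgery,1579488.00
myocardial_infarction,3090988.00
stroke_ischemic,2491671.00
stroke_ich,5156209.00
other_cv_event,2214259.00
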