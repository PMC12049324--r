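state,category,annual_count
LOW,gp_consultation,1
MODERATE,gp_consultation,12
HIGH,gp_consultation,12
VERY_HIGH,gp_consultation,0
ESKD,gp_consultation,0
LOW,nephrologist_consultation,0
MODERATE,nephrologist_consultation,2
HIGH,nephrologist_consultation,4
VERY_HIGH,nephrologist_consultation,12
ESKD,nephrologist_consultation,0
LOW,egfr_test,1
MODERATE,egfr_test,4
HIGH,egfr_test,8
VERY_HIGH,egfr_test,4
ESKD,egfr_test,4
LOW,urine_test,1
MODERATE,urine_test,2
HIGH,urine_test,4
VERY_HIGH,urine_test,4
ESKD,urine_test,4
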