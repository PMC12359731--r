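variable,type,mia,iac
n,count,53,89
male,present_count,11,20
solid_type,present_count,6,13
family_history,present_count,4,4
smoking,present_count,8,10
drinking,present_count,4,9
border_clear,present_count,4,2
lobulation,present_count,31,56
spiculation,present_count,27,44
vcs,present_count,9,40
pleural_indentation,present_count,20,37
vacuole,present_count,7,26
air_bronchogram,present_count,0,5
age_median,continuous,52,57
age_iqr,continuous,18.5,16
bmi_median,continuous,24.8,25.39
bmi_iqr,continuous,5.27,4.87
diameter_median,continuous,8,9
diameter_iqr,continuous,2.65,2
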