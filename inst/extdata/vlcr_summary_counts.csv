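variable,category,survivors,deaths
total,total,6419,285
cancer_type,NSCLC,5210,219
cancer_type,SCLC,1209,66
age_group,le60,1691,55
age_group,gt60,4728,230
seifa,most_disadvantaged,2377,126
seifa,second_quartile,1006,46
seifa,third_quartile,2075,86
seifa,least_disadvantaged,1063,35
mdm,no,2130,127
mdm,yes,4289,158
scs,no,3536,190
scs,yes,2883,95
ecog,good,4063,111
ecog,poor,593,67
ecog,not_stated,1763,107
stage,I,198,1
stage,II,469,2
stage,III,1376,25
stage,IV,3547,219
stage,not_stated,829,38
comorbidity,no,3071,113
comorbidity,yes,3348,172
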