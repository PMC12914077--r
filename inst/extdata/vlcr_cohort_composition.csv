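variable,category,n
cancer_type,NSCLC,5429
cancer_type,SCLC,1275
sex,male,3808
sex,female,2896
age_group,le60,1550
age_group,gt60,5154
mdm,no,2257
mdm,yes,4447
scs,no,3726
scs,yes,2978
ecog,good,4174
ecog,poor,660
ecog,not_stated,1870
comorbidity,no,3184
comorbidity,yes,3520
stage,I,199
stage,II,471
stage,III,1401
stage,IV,3766
stage,not_stated,867
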