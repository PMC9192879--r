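patient,age,followup_months,sex,dysmorphism,mandibular_advancement_mm,maxilla_advancement_mm,mandibular_setback_mm,maxilla_impaction_mm
1,27,12,M,III,NA,5,7,NA
2,37,14,M,III,NA,6,9,NA
3,20,15,F,III,NA,4,6,NA
4,22,13,M,III,NA,5,6,NA
5,25,15,F,III,NA,6,8,NA
6,32,12,F,III,NA,7,9,NA
7,21,12,M,III,NA,5,7,NA
8,25,13,F,II,8,NA,NA,4
9,23,13,M,III,NA,6,8,NA
10,32,13,M,III,NA,7,9,NA
11,19,12,M,III,NA,5,7,NA
12,22,12,M,II,9,NA,NA,5
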