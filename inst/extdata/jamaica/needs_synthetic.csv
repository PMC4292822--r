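condition,age_band,sex,rate,items_per_person_per_year
hypertension,all,all,0.3723932472691162,6
diabetes,all,all,0.1489572989076465,6
arthritis,all,all,0.1489572989076465,3
heart_disease,all,all,0.07447864945382325,6
copd,all,all,0.0595829195630586,5
renal_disease,all,all,0.0297914597815293,8
depression,all,all,0.07447864945382325,6
anxiety,all,all,0.08937437934458789,4
psychosis,all,all,0.01489572989076465,10
cancer,all,all,0.013406156901688183,8
hiv_aids,all,all,0.022343594836146972,9
influenza,all,all,0.1489572989076465,3
dengue_fever,all,all,0.007447864945382325,4
malaria,all,all,0.0014895729890764648,4
tuberculosis,all,all,0.0014895729890764648,5
rheumatic_fever,all,all,0.0014895729890764648,4
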