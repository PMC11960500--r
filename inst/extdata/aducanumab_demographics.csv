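category,level,value
total,reports,510
sex,female,254
sex,male,227
sex,unknown,29
age_group,<18,0
age_group,18-44,0
age_group,45-64,29
age_group,65-74,117
age_group,>=75,166
age_group,unknown,198
report_year,2016,18
report_year,2018,1
report_year,2019,2
report_year,2021,18
report_year,2022,224
report_year,2023,199
report_year,2024,48
reporter,consumer,212
reporter,not specified,3
reporter,pharmacist,120
reporter,physician,175
country,United States,473
country,Japan,10
country,Canada,5
country,France,4
country,Switzerland,4
country,Other,14
serious,serious,258
serious,non-serious,252
outcome,life-threatening,8
outcome,hospitalization,121
outcome,disability,2
outcome,death,29
outcome,congenital anomaly,0
outcome,required intervention,2
outcome,other,135
onset_bin,0-30,25
onset_bin,31-60,18
onset_bin,61-90,21
onset_bin,91-120,33
onset_bin,121-150,23
onset_bin,151-180,39
onset_bin,181-360,43
onset_bin,>360,15
weight,n,170
weight,missing,340
weight,mean,71.49
weight,sd,16.36
weight,median,69.62
weight,q1,60.80
weight,q3,80.30
weight,min,34.20
weight,max,132.00
event_total,events,1095
event_soc,Nervous system disorders,583
event_soc,"Injury, poisoning and procedural complications",84
event_soc,Psychiatric disorders,83
event_soc,General disorders and administration site conditions,75
event_soc,Gastrointestinal disorders,39
event_soc,Other,231
margin,drug_event_total,1095
margin,database_event_total,54336884
margin,demo_records,18278243
margin,drug_records,66418951
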