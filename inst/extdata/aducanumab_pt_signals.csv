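term,n,ror,ror_low,ror_high,prr,chi2,ic,ic_minus_2sd,ebgm,ebgm05
ARIA-E,141,53538.3,42177.8,67958.6,46644.4,3390009,14.55,6.83,24044.0,18942.0
ARIA-H,100,38187.9,29358.2,49673.2,34700.5,2041938,14.32,6.30,20420.9,15699.2
Headache,41,3.77,2.76,5.15,3.66,80.25,1.87,1.33,3.66,2.68
Confusional state,35,12.42,8.87,17.39,12.05,355.56,3.59,2.71,12.05,8.60
Cerebral haemorrhage,27,42.86,29.25,62.81,41.83,1075.76,5.39,3.54,41.79,28.52
Fall,23,3.95,2.61,5.97,3.89,49.58,1.96,1.20,3.89,2.57
Superficial siderosis of CNS,22,35937.4,20741.2,62267.2,35215.4,453124,14.33,3.80,20598.1,11888.2
Dementia Alzheimer's type,21,128.36,83.30,197.79,125.91,2596.15,6.97,3.61,125.60,81.51
Seizure,20,6.56,4.21,10.21,6.46,92.50,2.69,1.72,6.46,4.15
Amyloid related imaging abnormalities,17,17487.2,10039.7,30459.3,17215.7,217258,13.64,3.40,12781.6,7338.13
Cognitive disorder,13,16.05,9.29,27.73,15.87,181.19,3.99,2.17,15.86,9.18
Brain oedema,13,59.01,34.14,101.99,58.32,731.68,5.86,2.74,58.25,33.70
Memory impairment,12,4.89,2.77,8.63,4.84,36.68,2.28,1.10,4.84,2.74
Atrial fibrillation,11,6.35,3.50,11.50,6.29,49.06,2.65,1.29,6.29,3.47
Subarachnoid haemorrhage,9,48.94,25.39,94.34,48.54,418.73,5.60,2.16,48.50,25.16
Head injury,8,14.43,7.20,28.93,14.33,99.25,3.84,1.56,14.33,7.15
Cerebral microhaemorrhage,7,1493.95,702.77,3175.87,1484.41,10075.5,10.49,1.95,1441.32,678.01
Transient ischaemic attack,5,8.02,3.33,19.31,7.99,30.57,3.00,0.70,7.99,3.32
Mental status changes,5,10.00,4.15,24.07,9.96,40.30,3.32,0.82,9.95,4.13
Aphasia,4,7.20,2.70,19.22,7.18,21.28,2.84,0.39,7.18,2.69
Disorientation,4,5.49,2.06,14.66,5.48,14.64,2.45,0.24,5.47,2.05
Subdural haematoma,3,11.44,3.68,35.52,11.41,28.48,3.51,0.22,11.40,3.67
Skin cancer,3,7.94,2.56,24.67,7.92,18.15,2.99,0.09,7.92,2.55
Posterior reversible encephalopathy syndrome,3,17.14,5.52,53.22,17.09,45.44,4.09,0.32,17.09,5.50
Cerebral infarction,3,6.76,2.18,20.98,6.74,14.67,2.75,0.02,6.74,2.17
Haemorrhage intracranial,3,10.71,3.45,33.27,10.69,26.34,3.42,0.20,10.68,3.44
Ischaemic stroke,3,9.32,3.00,28.93,9.29,22.20,3.22,0.15,9.29,2.99
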