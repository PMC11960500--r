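soc,n,ror,ror_low,ror_high,prr,chi2,ic,ic_minus_2sd,ebgm,ebgm05
Nervous system disorders,352,10.82,8.97,13.05,4.04,971.65,2.01,1.80,4.04,3.35
"Injury, poisoning and procedural complications",63,0.24,0.19,0.32,0.34,129.25,-1.57,-1.94,0.34,0.26
Psychiatric disorders,58,1.13,0.86,1.48,1.11,0.73,0.15,-0.25,1.11,0.85
General disorders and administration site conditions,53,0.39,0.29,0.52,0.45,45.09,-1.14,-1.54,0.45,0.34
Gastrointestinal disorders,36,0.59,0.42,0.83,0.62,9.55,-0.69,-1.17,0.62,0.44
Infections and infestations,28,0.31,0.21,0.46,0.35,39.51,-1.51,-2.03,0.35,0.24
Investigations,20,0.66,0.42,1.04,0.68,3.27,-0.56,-1.19,0.68,0.43
Cardiac disorders,20,0.59,0.38,0.93,0.61,5.38,-0.72,-1.33,0.61,0.39
Musculoskeletal and connective tissue disorders,18,0.26,0.16,0.42,0.29,36.00,-1.79,-2.42,0.29,0.18
"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",16,0.27,0.16,0.44,0.29,30.60,-1.77,-2.42,0.29,0.18
Skin and subcutaneous tissue disorders,15,0.54,0.33,0.91,0.56,5.54,-0.84,-1.54,0.56,0.33
Metabolism and nutrition disorders,15,0.28,0.17,0.47,0.30,26.61,-1.72,-2.39,0.30,0.18
Vascular disorders,15,0.51,0.30,0.85,0.52,6.93,-0.94,-1.63,0.52,0.31
Renal and urinary disorders,13,0.58,0.34,1.01,0.60,3.74,-0.75,-1.49,0.60,0.34
"Respiratory, thoracic and mediastinal disorders",10,0.19,0.10,0.35,0.21,34.04,-2.28,-3.06,0.21,0.11
Eye disorders,9,0.43,0.22,0.84,0.44,6.57,-1.18,-2.02,0.44,0.23
Ear and labyrinth disorders,7,1.22,0.58,2.58,1.22,0.28,0.29,-0.78,1.22,0.58
Hepatobiliary disorders,3,0.14,0.05,0.45,0.15,15.26,-2.75,-3.86,0.15,0.05
Blood and lymphatic system disorders,3,0.27,0.09,0.84,0.28,5.86,-1.86,-3.02,0.28,0.09
Product issues,2,0.12,0.03,0.5,0.13,12.28,-2.97,-4.15,0.13,0.03
Immune system disorders,1,0.05,0.01,0.33,0.05,19.89,-4.39,-5.51,0.05,0.01
Reproductive system and breast disorders,1,0.10,0.01,0.68,0.10,8.58,-3.37,-4.55,0.10,0.01
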