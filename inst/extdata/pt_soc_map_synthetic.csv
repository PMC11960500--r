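pt,soc
ARIA-E,Nervous system disorders
ARIA-H,Nervous system disorders
Amyloid related imaging abnormalities,Nervous system disorders
Superficial siderosis of CNS,Nervous system disorders
Headache,Nervous system disorders
Cerebral haemorrhage,Nervous system disorders
Cerebral microhaemorrhage,Nervous system disorders
Cerebral infarction,Nervous system disorders
Haemorrhage intracranial,Nervous system disorders
Ischaemic stroke,Nervous system disorders
Subarachnoid haemorrhage,Nervous system disorders
Transient ischaemic attack,Nervous system disorders
Seizure,Nervous system disorders
Brain oedema,Nervous system disorders
Memory impairment,Nervous system disorders
Cognitive disorder,Nervous system disorders
Aphasia,Nervous system disorders
Mental status changes,Nervous system disorders
Dementia Alzheimer's type,Nervous system disorders
Posterior reversible encephalopathy syndrome,Nervous system disorders
Dizziness,Nervous system disorders
Confusional state,Psychiatric disorders
Disorientation,Psychiatric disorders
Insomnia,Psychiatric disorders
Fall,"Injury, poisoning and procedural complications"
Head injury,"Injury, poisoning and procedural complications"
Subdural haematoma,"Injury, poisoning and procedural complications"
Off label use,"Injury, poisoning and procedural complications"
Atrial fibrillation,Cardiac disorders
Skin cancer,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Nausea,Gastrointestinal disorders
Diarrhoea,Gastrointestinal disorders
Fatigue,General disorders and administration site conditions
Pyrexia,General disorders and administration site conditions
Drug ineffective,General disorders and administration site conditions
Rash,Skin and subcutaneous tissue disorders
Urinary tract infection,Infections and infestations
Arthralgia,Musculoskeletal and connective tissue disorders
Dyspnoea,"Respiratory, thoracic and mediastinal disorders"
Anaemia,Blood and lymphatic system disorders
Hypertension,Vascular disorders
Blood pressure increased,Investigations
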