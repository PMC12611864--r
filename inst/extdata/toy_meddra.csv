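pt,soc,baseline
Pyrexia,General disorders and administration site conditions,0.250
Injection site erythema,General disorders and administration site conditions,0.120
Injection site swelling,General disorders and administration site conditions,0.090
Injection site pain,General disorders and administration site conditions,0.070
Fatigue,General disorders and administration site conditions,0.030
Crying,General disorders and administration site conditions,0.110
Irritability,General disorders and administration site conditions,0.090
Seizure,Nervous system disorders,0.030
Febrile convulsion,Nervous system disorders,0.025
Hypotonia,Nervous system disorders,0.020
Somnolence,Nervous system disorders,0.050
Hypotonic-hyporesponsive episode,Nervous system disorders,0.012
Lethargy,Nervous system disorders,0.030
Tremor,Nervous system disorders,0.010
Opisthotonus,Nervous system disorders,0.004
Vomiting,Gastrointestinal disorders,0.080
Diarrhoea,Gastrointestinal disorders,0.060
Abdominal pain,Gastrointestinal disorders,0.015
Haematochezia,Gastrointestinal disorders,0.008
Flatulence,Gastrointestinal disorders,0.006
Rash,Skin and subcutaneous tissue disorders,0.060
Urticaria,Skin and subcutaneous tissue disorders,0.035
Erythema,Skin and subcutaneous tissue disorders,0.045
Pruritus,Skin and subcutaneous tissue disorders,0.015
Dermatitis,Skin and subcutaneous tissue disorders,0.008
Apnoea,Respiratory thoracic and mediastinal disorders,0.020
Dyspnoea,Respiratory thoracic and mediastinal disorders,0.015
Cough,Respiratory thoracic and mediastinal disorders,0.012
Respiratory distress,Respiratory thoracic and mediastinal disorders,0.008
Rhinorrhoea,Respiratory thoracic and mediastinal disorders,0.010
Cyanosis,Cardiac disorders,0.018
Bradycardia,Cardiac disorders,0.006
Tachycardia,Cardiac disorders,0.008
Pallor,Vascular disorders,0.020
Flushing,Vascular disorders,0.008
Shock,Vascular disorders,0.003
Decreased appetite,Metabolism and nutrition disorders,0.040
Dehydration,Metabolism and nutrition disorders,0.010
Feeding disorder,Metabolism and nutrition disorders,0.012
Otitis media,Infections and infestations,0.008
Nasopharyngitis,Infections and infestations,0.012
Bronchiolitis,Infections and infestations,0.006
Body temperature increased,Investigations,0.050
Platelet count increased,Investigations,0.004
Blood potassium increased,Investigations,0.003
White blood cell count increased,Investigations,0.006
Screaming,Psychiatric disorders,0.030
Restlessness,Psychiatric disorders,0.020
Anaphylactic reaction,Immune system disorders,0.004
Hypersensitivity,Immune system disorders,0.010
Incorrect dose administered,Injury poisoning and procedural complications,0.010
Wrong product administered,Injury poisoning and procedural complications,0.006
Expired product administered,Injury poisoning and procedural complications,0.004
Product preparation issue,Injury poisoning and procedural complications,0.003
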