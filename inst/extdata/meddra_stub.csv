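pt,pt_code,soc,soc_code
Myalgia,10028411,Musculoskeletal and connective tissue disorders,10028395
Muscle fatigue,10049565,Musculoskeletal and connective tissue disorders,10028395
Pain in extremity,10033425,Musculoskeletal and connective tissue disorders,10028395
Arthralgia,10003239,Musculoskeletal and connective tissue disorders,10028395
Muscle spasms,10028334,Musculoskeletal and connective tissue disorders,10028395
Rhabdomyolysis,10039020,Musculoskeletal and connective tissue disorders,10028395
Musculoskeletal stiffness,10052904,Musculoskeletal and connective tissue disorders,10028395
Back pain,10003988,Musculoskeletal and connective tissue disorders,10028395
Blood creatine phosphokinase increased,10005470,Investigations,10022891
Blood creatinine increased,10005483,Investigations,10022891
Blood creatine increased,10005464,Investigations,10022891
Prothrombin time prolonged,10037063,Investigations,10022891
Hepatic enzyme increased,10019705,Investigations,10022891
Blood glucose decreased,10005555,Investigations,10022891
Weight decreased,10047895,Investigations,10022891
Blood triglycerides increased,10005839,Investigations,10022891
Liver function test abnormal,10024690,Investigations,10022891
Gout,10018627,Metabolism and nutrition disorders,10027433
Hypoglycaemia,10020993,Metabolism and nutrition disorders,10027433
Decreased appetite,10061428,Metabolism and nutrition disorders,10027433
Dehydration,10012174,Metabolism and nutrition disorders,10027433
Dyspepsia,10013946,Gastrointestinal disorders,10017947
Nausea,10028813,Gastrointestinal disorders,10017947
Diarrhoea,10012735,Gastrointestinal disorders,10017947
Abdominal pain,10000081,Gastrointestinal disorders,10017947
Vomiting,10047700,Gastrointestinal disorders,10017947
Constipation,10010774,Gastrointestinal disorders,10017947
Pancreatitis,10033645,Gastrointestinal disorders,10017947
Pancreatitis acute,10033647,Gastrointestinal disorders,10017947
Abdominal distension,10000060,Gastrointestinal disorders,10017947
Headache,10019211,Nervous system disorders,10029205
Dizziness,10013573,Nervous system disorders,10029205
Somnolence,10041349,Nervous system disorders,10029205
Paraesthesia,10033775,Nervous system disorders,10029205
Fatigue,10016256,General disorders and administration site conditions,10018065
Asthenia,10003549,General disorders and administration site conditions,10018065
Pyrexia,10037660,General disorders and administration site conditions,10018065
Malaise,10025482,General disorders and administration site conditions,10018065
Oedema peripheral,10030124,General disorders and administration site conditions,10018065
Chest pain,10008479,General disorders and administration site conditions,10018065
Drug ineffective,10013709,General disorders and administration site conditions,10018065
Rash,10037844,Skin and subcutaneous tissue disorders,10040785
Photosensitivity reaction,10034972,Skin and subcutaneous tissue disorders,10040785
Pruritus,10037087,Skin and subcutaneous tissue disorders,10040785
Urticaria,10046735,Skin and subcutaneous tissue disorders,10040785
Alopecia,10001760,Skin and subcutaneous tissue disorders,10040785
Renal impairment,10062237,Renal and urinary disorders,10038359
Renal failure,10038435,Renal and urinary disorders,10038359
Acute kidney injury,10069339,Renal and urinary disorders,10038359
Hepatitis,10019717,Hepatobiliary disorders,10019805
Cholelithiasis,10008629,Hepatobiliary disorders,10019805
Hepatotoxicity,10019851,Hepatobiliary disorders,10019805
Hepatic steatosis,10019708,Hepatobiliary disorders,10019805
Eye opacity,10015922,Eye disorders,10015919
Vision blurred,10047513,Eye disorders,10015919
Anaemia,10002034,Blood and lymphatic system disorders,10005329
Thrombocytopenia,10043554,Blood and lymphatic system disorders,10005329
Hypersensitivity,10020751,Immune system disorders,10021428
Anaphylactic reaction,10002198,Immune system disorders,10021428
Insomnia,10022437,Psychiatric disorders,10037175
Anxiety,10002855,Psychiatric disorders,10037175
Interstitial lung disease,10022611,"Respiratory, thoracic and mediastinal disorders",10038738
Dyspnoea,10013968,"Respiratory, thoracic and mediastinal disorders",10038738
Palpitations,10033557,Cardiac disorders,10007541
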