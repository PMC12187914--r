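pt	soc
Sopor	Psychiatric disorders
Drug abuse	Psychiatric disorders
Confusional state	Psychiatric disorders
Agitation	Psychiatric disorders
Insomnia	Psychiatric disorders
Anxiety	Psychiatric disorders
Depression	Psychiatric disorders
Memory impairment	Psychiatric disorders
Somnolence	Nervous system disorders
Sedation	Nervous system disorders
Tremor	Nervous system disorders
Dizziness	Nervous system disorders
Headache	Nervous system disorders
Syncope	Nervous system disorders
Coma	Nervous system disorders
Tachycardia	Cardiac disorders
Bradycardia	Cardiac disorders
Hypotension	Cardiac disorders
Palpitations	Cardiac disorders
Poisoning	Injury, poisoning and procedural complications
Fall	Injury, poisoning and procedural complications
Overdose	Injury, poisoning and procedural complications
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Dry mouth	Gastrointestinal disorders
Fatigue	General disorders and administration site conditions
Asthenia	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Cough	Respiratory, thoracic and mediastinal disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Myalgia	Musculoskeletal and connective tissue disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Hyperhidrosis	Skin and subcutaneous tissue disorders
Weight decreased	Investigations
Blood pressure increased	Investigations
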