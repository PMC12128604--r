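pt	soc	primary_flag
Hypertension	Vascular disorders	Y
Headache	Nervous system disorders	Y
Nausea	Gastrointestinal disorders	Y
Vomiting	Gastrointestinal disorders	Y
Diarrhoea	Gastrointestinal disorders	Y
Proteinuria	Renal and urinary disorders	Y
Proteinuria	Investigations	N
Renal impairment	Renal and urinary disorders	Y
Blood creatinine increased	Investigations	Y
Glomerular filtration rate decreased	Investigations	Y
Arthralgia	Musculoskeletal and connective tissue disorders	Y
Alopecia	Skin and subcutaneous tissue disorders	Y
Dizziness	Nervous system disorders	Y
Urinary tract infection	Infections and infestations	Y
Insomnia	Psychiatric disorders	Y
Fatigue	General disorders and administration site conditions	Y
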