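pt,soc_name,soc_code
SEIZURE,Nervous system disorders,10029205
PARTIAL SEIZURES,Nervous system disorders,10029205
SIMPLE PARTIAL SEIZURES,Nervous system disorders,10029205
DIZZINESS,Nervous system disorders,10029205
HEADACHE,Nervous system disorders,10029205
SOMNOLENCE,Nervous system disorders,10029205
BALANCE DISORDER,Nervous system disorders,10029205
MEMORY IMPAIRMENT,Nervous system disorders,10029205
AMNESIA,Nervous system disorders,10029205
HYPONATRAEMIA,Metabolism and nutrition disorders,10027433
INCREASED APPETITE,Metabolism and nutrition disorders,10027433
AGGRESSION,Psychiatric disorders,10037175
AGITATION,Psychiatric disorders,10037175
IRRITABILITY,Psychiatric disorders,10037175
CONFUSIONAL STATE,Psychiatric disorders,10037175
ABNORMAL BEHAVIOUR,Psychiatric disorders,10037175
INSOMNIA,Psychiatric disorders,10037175
SUICIDAL IDEATION,Psychiatric disorders,10037175
NAUSEA,Gastrointestinal disorders,10017947
VOMITING,Gastrointestinal disorders,10017947
FATIGUE,General disorders and administration site conditions,10018065
DRUG INEFFECTIVE,General disorders and administration site conditions,10018065
DIPLOPIA,Eye disorders,10015919
EYE MOVEMENT DISORDER,Eye disorders,10015919
FALL,"Injury, poisoning and procedural complications",10022117
OVERDOSE,"Injury, poisoning and procedural complications",10022117
WEIGHT DECREASED,Investigations,10022891
RASH,Skin and subcutaneous tissue disorders,10040785
RASH MACULO-PAPULAR,Skin and subcutaneous tissue disorders,10040785
DERMATITIS EXFOLIATIVE,Skin and subcutaneous tissue disorders,10040785
TOXIC SKIN ERUPTION,Skin and subcutaneous tissue disorders,10040785
STEVENS-JOHNSON SYNDROME,Skin and subcutaneous tissue disorders,10040785
DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS,Skin and subcutaneous tissue disorders,10040785
TOXIC EPIDERMAL NECROLYSIS,Skin and subcutaneous tissue disorders,10040785
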