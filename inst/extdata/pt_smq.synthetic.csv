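pt,smq_name,smq_code,scope
SEIZURE,Convulsions,20000079,narrow
PARTIAL SEIZURES,Convulsions,20000079,narrow
SIMPLE PARTIAL SEIZURES,Convulsions,20000079,narrow
HYPONATRAEMIA,Hyponatraemia/SIADH,20000141,narrow
CONFUSIONAL STATE,Hyponatraemia/SIADH,20000141,broad
OVERDOSE,Medication errors,20000224,narrow
SUICIDAL IDEATION,Depression and suicide/self-injury,20000035,narrow
DERMATITIS EXFOLIATIVE,Hypersensitivity,20000214,narrow
TOXIC SKIN ERUPTION,Hypersensitivity,20000214,narrow
STEVENS-JOHNSON SYNDROME,Hypersensitivity,20000214,narrow
DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS,Hypersensitivity,20000214,narrow
RASH MACULO-PAPULAR,Hypersensitivity,20000214,narrow
DERMATITIS EXFOLIATIVE,Severe cutaneous adverse reactions,20000020,narrow
STEVENS-JOHNSON SYNDROME,Severe cutaneous adverse reactions,20000020,narrow
TOXIC SKIN ERUPTION,Severe cutaneous adverse reactions,20000020,narrow
DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS,Severe cutaneous adverse reactions,20000020,narrow
RASH,Hypersensitivity,20000214,broad
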