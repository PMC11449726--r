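# Synthetic stand-in for a regulator-maintained designated-medical-events
# list: rare, serious, drug-attributable events warranting scrutiny
# regardless of statistical strength. One PT per line.
DERMATITIS EXFOLIATIVE
STEVENS-JOHNSON SYNDROME
DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS
TOXIC EPIDERMAL NECROLYSIS
AGRANULOCYTOSIS
ANAPHYLACTIC REACTION
ACUTE HEPATIC FAILURE
APLASTIC ANAEMIA
TORSADE DE POINTES
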