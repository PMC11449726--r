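# Events listed in the target drug's label ("instructions"); user-supplied
# screening metadata, synthetic subset for the bundled examples.
SUICIDAL IDEATION
STEVENS-JOHNSON SYNDROME
DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS
TOXIC SKIN ERUPTION
DERMATITIS EXFOLIATIVE
RASH MACULO-PAPULAR
HYPONATRAEMIA
SOMNOLENCE
BALANCE DISORDER
MEMORY IMPAIRMENT
AMNESIA
DIPLOPIA
EYE MOVEMENT DISORDER
DIZZINESS
HEADACHE
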