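# Referent names for the target drug (generic, trade and development names)
ESLICARBAZEPINE ACETATE
ESLICARBAZEPINE
APTIOM
ZEBINIX
EXALIEF
STEDESA
BIA 2-093
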