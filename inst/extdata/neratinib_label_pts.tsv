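pt
diarrhoea
nausea
fatigue
vomiting
decreased appetite
dehydration
abdominal pain
dyspepsia
muscle spasms
abdominal distension
dry mouth
stomatitis
skin fissures
nail disorder
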