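pattern	canonical
neratinib	neratinib
nerlynx	neratinib
neratinib maleate	neratinib
hki-272	neratinib
hki 272	neratinib
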