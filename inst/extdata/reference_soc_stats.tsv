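term	a	ror	ror_lo	ror_hi	prr	prr_lo	prr_hi	chisq	ic	ic025	ebgm	ebgm05
gastrointestinal disorders	2564	7.14	6.79	7.5	4.71	4.53	4.9	8181.8	2.24	2.17	4.71	4.52
metabolism and nutrition disorders	333	2.58	2.31	2.88	2.5	2.27	2.76	305.94	1.32	1.16	2.5	2.28
investigations	308	0.77	0.69	0.87	0.78	0.69	0.88	19.6	-0.35	-0.52	0.78	0.71
skin and subcutaneous tissue disorders	311	0.77	0.69	0.87	0.78	0.69	0.88	19.88	-0.35	-0.52	0.78	0.71
general disorders and administration site conditions	958	0.77	0.72	0.83	0.8	0.75	0.85	55.87	-0.31	-0.41	0.8	0.76
nervous system disorders	375	0.71	0.64	0.79	0.73	0.66	0.81	40.96	-0.46	-0.61	0.73	0.67
neoplasms benign, malignant and unspecified (incl cysts and polyps)	160	0.68	0.58	0.79	0.69	0.59	0.81	23.78	-0.54	-0.77	0.69	0.6
hepatobiliary disorders	35	0.62	0.45	0.87	0.63	0.45	0.88	7.91	-0.68	-1.15	0.63	0.47
injury, poisoning and procedural complications	474	0.58	0.53	0.64	0.61	0.56	0.66	129.64	-0.7	-0.84	0.62	0.57
musculoskeletal and connective tissue disorders	207	0.58	0.51	0.67	0.6	0.52	0.69	59.34	-0.74	-0.94	0.6	0.53
renal and urinary disorders	78	0.55	0.44	0.69	0.56	0.45	0.69	28.02	-0.84	-1.16	0.56	0.46
respiratory, thoracic and mediastinal disorders	170	0.54	0.46	0.63	0.55	0.47	0.64	65.15	-0.86	-1.08	0.55	0.49
infections and infestations	202	0.53	0.46	0.61	0.55	0.48	0.63	80.56	-0.87	-1.07	0.55	0.49
reproductive system and breast disorders	23	0.52	0.34	0.78	0.52	0.34	0.78	10.24	-0.94	-1.52	0.52	0.37
blood and lymphatic system disorders	56	0.49	0.38	0.64	0.49	0.38	0.63	29.45	-1.02	-1.39	0.49	0.4
ear and labyrinth disorders	11	0.38	0.21	0.69	0.38	0.21	0.68	10.99	-1.39	-2.2	0.38	0.23
vascular disorders	48	0.37	0.28	0.49	0.37	0.28	0.49	51.18	-1.42	-1.82	0.37	0.3
endocrine disorders	6	0.34	0.15	0.76	0.34	0.15	0.76	7.64	-1.55	-2.62	0.34	0.17
eye disorders	43	0.33	0.24	0.44	0.33	0.25	0.44	59.24	-1.59	-2.02	0.33	0.26
psychiatric disorders	95	0.25	0.2	0.3	0.26	0.21	0.32	212.5	-1.95	-2.24	0.26	0.22
cardiac disorders	20	0.14	0.09	0.22	0.14	0.09	0.22	103.6	-2.79	-3.41	0.14	0.1
immune system disorders	11	0.13	0.07	0.24	0.13	0.07	0.23	63.7	-2.92	-3.74	0.13	0.08
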