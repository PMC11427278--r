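term	soc	a	ror	ror_lo	ror_hi	prr	prr_lo	prr_hi	chisq	ic	ic025	ebgm	ebgm05	on_label
diarrhoea	gastrointestinal disorders	991	15.92	14.88	17.04	13.64	12.86	14.47	11703.35	3.77	3.67	13.6	12.85	TRUE
nausea	gastrointestinal disorders	438	5.8	5.26	6.39	5.48	4.97	6.04	1620.94	2.45	2.31	5.47	5.04	TRUE
fatigue	general disorders and administration site conditions	361	4.25	3.82	4.73	4.07	3.69	4.49	847.05	2.02	1.87	4.07	3.72	TRUE
vomiting	gastrointestinal disorders	223	5	4.38	5.72	4.87	4.25	5.59	688.95	2.28	2.09	4.86	4.35	TRUE
constipation	gastrointestinal disorders	221	9.83	8.59	11.24	9.53	8.31	10.93	1688.92	3.25	3.06	9.51	8.5	FALSE
decreased appetite	metabolism and nutrition disorders	170	6.8	5.84	7.92	6.65	5.68	7.78	817.29	2.73	2.51	6.64	5.84	TRUE
dehydration	metabolism and nutrition disorders	102	8.48	6.98	10.32	8.37	6.88	10.18	661.46	3.06	2.78	8.35	7.09	TRUE
abdominal pain	gastrointestinal disorders	93	4.05	3.3	4.97	4	3.29	4.87	210.23	2	1.71	4	3.37	TRUE
abdominal pain upper	gastrointestinal disorders	88	4.19	3.39	5.17	4.14	3.34	5.14	210.42	2.05	1.75	4.14	3.47	FALSE
abdominal discomfort	gastrointestinal disorders	65	3.26	2.55	4.16	3.24	2.56	4.1	100.84	1.69	1.34	3.24	2.64	FALSE
dyspepsia	gastrointestinal disorders	63	6.73	5.25	8.63	6.68	5.18	8.62	304.1	2.74	2.38	6.67	5.42	TRUE
muscle spasms	musculoskeletal and connective tissue disorders	61	3.34	2.6	4.3	3.32	2.57	4.28	99.07	1.73	1.37	3.32	2.69	TRUE
abdominal distension	gastrointestinal disorders	51	4.96	3.76	6.53	4.92	3.74	6.47	159.55	2.3	1.9	4.92	3.91	TRUE
disease progression	general disorders and administration site conditions	43	3.41	2.53	4.61	3.4	2.53	4.56	72.78	1.76	1.34	3.39	2.64	FALSE
underdose	injury, poisoning and procedural complications	43	4.7	3.48	6.34	4.67	3.48	6.27	124.18	2.22	1.8	4.67	3.63	FALSE
dry mouth	gastrointestinal disorders	39	5.18	3.78	7.1	5.16	3.77	7.06	130.7	2.37	1.92	5.15	3.96	TRUE
gastrooesophageal reflux disease	gastrointestinal disorders	37	4.68	3.39	6.47	4.66	3.41	6.38	106.51	2.22	1.76	4.66	3.56	FALSE
adverse drug reaction	general disorders and administration site conditions	35	3.22	2.31	4.49	3.21	2.3	4.48	53.27	1.68	1.21	3.21	2.43	FALSE
breast cancer metastatic	neoplasms benign, malignant and unspecified (incl cysts and polyps)	33	33.46	23.7	47.17	33.29	23.86	46.45	1025.66	5.05	4.56	33.04	24.79	FALSE
prescribed underdose	injury, poisoning and procedural complications	30	9.67	6.75	13.84	9.63	6.77	13.7	231.46	3.26	2.75	9.61	7.11	FALSE
stomatitis	gastrointestinal disorders	29	4.22	2.93	6.08	4.21	2.9	6.11	70.95	2.07	1.55	4.21	3.1	TRUE
blood potassium decreased	investigations	28	9.46	6.52	13.71	9.42	6.49	13.67	210.32	3.23	2.71	9.4	6.89	FALSE
metastases to central nervous system	neoplasms benign, malignant and unspecified (incl cysts and polyps)	24	17.22	11.52	25.73	17.16	11.6	25.4	363.77	4.1	3.53	17.09	12.21	FALSE
flatulence	gastrointestinal disorders	23	4.18	2.77	6.29	4.16	2.76	6.28	55.3	2.06	1.48	4.16	2.95	FALSE
hypokalaemia	metabolism and nutrition disorders	16	3.38	2.07	5.52	3.37	2.06	5.5	26.71	1.75	1.07	3.37	2.24	FALSE
onychoclasis	skin and subcutaneous tissue disorders	13	15.3	8.87	26.39	15.27	8.82	26.44	172.76	3.93	3.17	15.22	9.64	FALSE
skin fissures	skin and subcutaneous tissue disorders	13	6.1	3.54	10.51	6.09	3.52	10.54	55.18	2.6	1.85	6.08	3.85	TRUE
dermatitis acneiform	skin and subcutaneous tissue disorders	8	13.05	6.52	26.14	13.04	6.57	25.89	88.65	3.7	2.76	13	7.27	FALSE
gastrointestinal sounds abnormal	gastrointestinal disorders	7	13.73	6.54	28.85	13.72	6.51	28.89	82.28	3.77	2.77	13.68	7.35	FALSE
faeces soft	gastrointestinal disorders	6	6.16	2.76	13.72	6.16	2.76	13.76	25.87	2.62	1.55	6.15	3.14	FALSE
nail disorder	skin and subcutaneous tissue disorders	6	6.96	3.13	15.52	6.96	3.12	15.55	30.56	2.8	1.73	6.95	3.55	TRUE
breast cancer stage iv	neoplasms benign, malignant and unspecified (incl cysts and polyps)	6	9.88	4.43	22.02	9.87	4.42	22.05	47.73	3.3	2.23	9.85	5.04	FALSE
metastases to lung	neoplasms benign, malignant and unspecified (incl cysts and polyps)	6	4.67	2.1	10.41	4.67	2.09	10.43	17.28	2.22	1.15	4.66	2.39	FALSE
nasal dryness	respiratory, thoracic and mediastinal disorders	6	9.58	4.3	21.36	9.58	4.29	21.4	45.98	3.26	2.19	9.56	4.89	FALSE
brain neoplasm	neoplasms benign, malignant and unspecified (incl cysts and polyps)	5	4.98	2.07	11.97	4.98	2.06	12.03	15.87	2.31	1.16	4.97	2.39	FALSE
blood magnesium decreased	investigations	5	5.15	2.14	12.38	5.15	2.13	12.44	16.68	2.36	1.21	5.14	2.47	FALSE
enteritis	gastrointestinal disorders	4	5.23	1.96	13.96	5.23	1.96	13.94	13.67	2.39	1.12	5.23	2.3	FALSE
early satiety	general disorders and administration site conditions	4	29.42	11	78.69	29.4	11.03	78.34	108.99	4.87	3.6	29.21	12.82	FALSE
paronychia	infections and infestations	4	8.15	3.05	21.73	8.14	3.06	21.69	25.01	3.02	1.76	8.13	3.58	FALSE
faeces pale	gastrointestinal disorders	3	14.37	4.62	44.66	14.36	4.61	44.76	37.17	3.84	2.42	14.32	5.54	FALSE
gastrointestinal toxicity	gastrointestinal disorders	3	5.71	1.84	17.73	5.71	1.83	17.8	11.64	2.51	1.1	5.7	2.21	FALSE
faecaloma	gastrointestinal disorders	3	5.54	1.78	17.18	5.53	1.77	17.24	11.13	2.47	1.05	5.53	2.14	FALSE
onycholysis	skin and subcutaneous tissue disorders	3	16.05	5.16	49.89	16.04	5.15	49.99	42.16	4	2.58	15.99	6.19	FALSE
nail discolouration	skin and subcutaneous tissue disorders	3	7.01	2.26	21.75	7	2.25	21.82	15.42	2.81	1.39	6.99	2.71	FALSE
metastatic neoplasm	neoplasms benign, malignant and unspecified (incl cysts and polyps)	3	7.68	2.47	23.83	7.67	2.46	23.91	17.38	2.94	1.52	7.66	2.97	FALSE
wound haemorrhage	injury, poisoning and procedural complications	3	6.9	2.22	21.43	6.9	2.21	21.51	15.11	2.78	1.37	6.89	2.67	FALSE
breast cellulitis	infections and infestations	3	106.74	33.92	335.84	106.69	34.23	332.53	306.24	6.7	5.26	104.04	39.87	FALSE
bladder spasm	renal and urinary disorders	3	19.54	6.28	60.77	19.53	6.27	60.87	52.51	4.28	2.86	19.45	7.53	FALSE
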