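block	category	n	pct
year	2017	56	3.63
year	2018	765	49.55
year	2019	190	12.31
year	2020	193	12.50
year	2021	153	9.91
year	2022	84	5.44
year	2023	103	6.67
sex	Female	50	3.24
sex	Male	2	0.13
sex	Unknown	1492	96.63
age	18-45	10	0.65
age	45-65	28	1.81
age	65-75	2	0.13
age	>=75	3	0.19
age	Unknown	1501	97.22
reporter	Pharmacist	773	50.06
reporter	Other health-professional	447	28.95
reporter	Consumer	199	12.89
reporter	Physician	115	7.45
reporter	Lawyer	3	0.19
reporter	Unknown	7	0.45
country	United States	1321	85.56
country	Argentina	51	3.30
country	Other	172	11.14
outcome	Hospitalization	315	37.28
outcome	Death	191	22.60
outcome	Life threatening	10	1.18
outcome	Disability	4	0.47
outcome	Required intervention	1	0.12
outcome	Other serious	324	38.34
tto	<7	185	14.27
tto	7-28	74	5.71
tto	28-60	41	3.16
tto	>=60	58	4.48
tto	Unknown	938	72.38
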