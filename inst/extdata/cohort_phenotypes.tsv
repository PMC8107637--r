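individual	family	sex	age_presentation	optic_atrophy	retinal_dystrophy	macula_edema	retinal_vessels_attenuation	cataract	nystagmus	squint	constricted_visual_field	nyctalopia	hearing_impairment	ataxia	sensory_neuropathy	motor_neuropathy	dizziness	tremor
1.1	1	M	3 y	Yes (3)	No	No	No	No	Yes (3)	Yes (3)	No	No	No	Yes (11)	No	No	Yes (11)	Yes (12)
2.1	2	M	4 y	Yes (11)	Yes (4)	Yes (5)	Yes (11)	Yes (11)	No	No	Yes	Yes	Yes (11)	Yes (late teens)	Yes (late teens)	Yes (late teens)	No	No
2.2	2	M	14 y	Yes (14)	Yes (14)	No	Yes (14)	No	No	No	Yes	No	Yes (late teens)	Yes (late teens)	Yes (late teens)	Yes (late teens)	No	No
3.1	3	M	7 y	Yes (7)	Yes (7)	No	Yes (8)	Yes (18)	Yes (14)	Yes (16)	Yes	Yes	Yes (20)	No	No	No	Yes (late teens)	Yes (15)
4.1	4	M	22 y	Yes (25)	No	No	No	No	No	No	No	No	No	No	Yes (22)	Yes (22)	No	No
5.1	5	F	40s	Yes (40s)	No	No	No	No	No	No	No	No	Yes (40s)	Yes (40s)	Yes (40s)	Yes (40s)	No	No
6.1	6	M	Childhood	Yes (>7)	Yes (7)	No	No	Yes (17 to 18)	Yes (>7)	No	ND	ND	No	Yes (childhood)	Yes (childhood)	No	No	No
7.1	7	M	2.5 years	Yes (7)	Yes (7)	Yes (17)	Yes (ND)	No	No	No	Yes	ND	No	Yes (2.5)	No	No	No	No
7.2	7	F	3.5 y	Yes (3.5)	Yes (3.5)	No	No	No	No	No	Yes	ND	No	Yes (15)	No	No	No	No
8.1	8	F	42 y	Yes (42)	Possible	No	No	No	No	No	ND	ND	Yes (42)	Yes (42)	Yes (42)	Yes (42)	No	No
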