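id	type	offset	leader_aa_len	annot
V01	V	1	4	AK
V02	V	1	2	AR
V03	V	1	5	AT
V04	V	2	5	AR
V05	V	1	3	AR
V06	V	2	2	AR
V07	V	2	4	AT
V08	V	0	5	AR
V09	V	2	2	AK
V10	V	1	3	AK
V11	V	1	3	AR
V12	V	1	4	AK
V13	V	1	4	AT
V14	V	2	5	AK
V15	V	1	2	AT
D01	D	0	0	
D02	D	0	0	
D03	D	0	0	
D04	D	0	0	
D05	D	0	0	
D06	D	0	0	
D07	D	0	0	
D08	D	0	0	
D09	D	0	0	
D10	D	0	0	
J1	J	0	0	DA
J2	J	0	0	DA
J3	J	0	0	DA
J4	J	0	0	DA
J5	J	0	0	DS
J6	J	0	0	EA
C1	C1	0	0	
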