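group	profile	class	count
G1	3	down	75
G1	0	down	67
G1	1	down	15
G1	6	up	40
G1	7	up	12
G1	4	up	1
G1		peak	9
G1		valley	7
G2	3	down	42
G2	1	down	34
G2	0	down	15
G2	6	up	35
G2	4	up	25
G2	7	up	4
G2		valley	95
G2		peak	23
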