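# SYNTHETIC reconstruction of the lipid-facing (TM_out) instantaneous
# substitution rates, transcribed from the published narrative description
# of the rate pattern (display units: 1e4 x expected changes per 100 sites).
# Pairs not mentioned in the narrative are set to 0.  Where the narrative
# states a pair twice with different values, the larger value is kept.
# This is NOT the full published supplementary rate matrix.
a	b	rate
V	I	275
V	L	168
V	A	61
V	F	22
V	T	6
L	I	82
L	A	16
L	M	16
L	F	65
L	W	4
L	Y	4
L	T	3
I	F	10
I	A	8
I	M	4
A	G	46
A	F	7
A	T	22
A	S	6
Y	F	20
Y	W	18
Y	H	3
W	F	5
T	G	4
T	S	7
S	G	3
F	M	4
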