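original_group	merged	ambiguous	note
1-4-D-I	A	FALSE	
0-F-K-R	B	FALSE	
3-G-H	C	FALSE	
6-7-9-Q	D	FALSE	
10-B-C-S-U	E	TRUE	token '10' matches no single area code; recorded verbatim, not interpreted
2-E	F	FALSE	
M-N	G	FALSE	
O-P	H	FALSE	
L	I	FALSE	
V	J	FALSE	
8	K	FALSE	
I	L	TRUE	area I also appears in group 1-4-D-I; conflicting as printed
C	M	TRUE	area C also appears in group 10-B-C-S-U; conflicting as printed
5	N	FALSE	
Ctenoblepharys	O	FALSE	new area defined for this genus, absent from the endemism areas
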