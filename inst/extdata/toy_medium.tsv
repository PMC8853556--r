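species	group	conc
glc_e	g1	25
gln_e	g1	4
n1_e	g1	5
n2_e	g1	5
glc_e	g2	25
gln_e	g2	4
n1_e	g2	10
n2_e	g2	10
glc_e	g3	25
gln_e	g3	4
n1_e	g3	20
n2_e	g3	20
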