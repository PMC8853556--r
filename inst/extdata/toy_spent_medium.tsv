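group	bioRep	techRep	metabolite	t0	t48
g1	1	1	glucose	25	15
g1	1	1	glutamine	4	2
g1	1	1	lactate	0	17.1
g1	1	1	glutamate	0	0.38
g1	1	2	glucose	25	15
g1	1	2	glutamine	4	2
g1	1	2	lactate	0	17.1
g1	1	2	glutamate	0	0.38
g1	2	1	glucose	25	15
g1	2	1	glutamine	4	2
g1	2	1	lactate	0	18.9
g1	2	1	glutamate	0	0.42
g1	2	2	glucose	25	15
g1	2	2	glutamine	4	2
g1	2	2	lactate	0	18.9
g1	2	2	glutamate	0	0.42
g2	1	1	glucose	25	15
g2	1	1	glutamine	4	2
g2	1	1	lactate	0	17.1
g2	1	1	glutamate	0	0.38
g2	1	2	glucose	25	15
g2	1	2	glutamine	4	2
g2	1	2	lactate	0	17.1
g2	1	2	glutamate	0	0.38
g2	2	1	glucose	25	15
g2	2	1	glutamine	4	2
g2	2	1	lactate	0	18.9
g2	2	1	glutamate	0	0.42
g2	2	2	glucose	25	15
g2	2	2	glutamine	4	2
g2	2	2	lactate	0	18.9
g2	2	2	glutamate	0	0.42
g3	1	1	glucose	25	15
g3	1	1	glutamine	4	2
g3	1	1	lactate	0	17.1
g3	1	1	glutamate	0	0.38
g3	1	2	glucose	25	15
g3	1	2	glutamine	4	2
g3	1	2	lactate	0	17.1
g3	1	2	glutamate	0	0.38
g3	2	1	glucose	25	15
g3	2	1	glutamine	4	2
g3	2	1	lactate	0	18.9
g3	2	1	glutamate	0	0.42
g3	2	2	glucose	25	15
g3	2	2	glutamine	4	2
g3	2	2	lactate	0	18.9
g3	2	2	glutamate	0	0.42
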