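metabolite	g1__s1	g1__s2	g1__s3	g2__s1	g2__s2	g2__s3	g3__s1	g3__s2	g3__s3
glc_c	44.497	44.679	48.498	61.225	47.656	47.89	48.94	49.761	46.664
pyr_c	46.152	54.983	43.145	55.134	45.35	51.83	51.888	46.712	52.671
lac_c	61.298	46.754	49.037	56.138	48.877	58.904	47.799	48.083	49.454
gln_c	49.837	43.319	50.794	43.987	51.791	58.305	43.38	44.317	49.265
glu_c	43.746	59.976	62.666	54.894	46.24	48.131	54.916	59.581	52.62
akg_c	42.223	51.911	50.28	50.857	54.058	39.587	57.916	48.13	44.185
cit	52.042	48.577	52.077	42.961	44.089	63.866	48.238	42.371	55.518
icit_c	49.658	55.305	49.368	52.411	44.801	53.183	43.89	50.741	49.724
w_c	48.193	54.362	48.116	48.967	57.463	52.518	53.051	51.077	53.397
n1_c	45.335	46.763	49.578	115.195	89.89	99.368	198.115	180.32	220.683
n2_c	42.874	62.031	53.828	92.163	103.686	104.709	167.335	149.071	203.5
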