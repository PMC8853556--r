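gene	g1__s1	g1__s2	g1__s3	g2__s1	g2__s2	g2__s3	g3__s1	g3__s2	g3__s3
gACO1	93.459	99.34	103.434	98.39	92.374	94.001	87.576	114.824	92.945
gCS	101.345	109.35	98.967	108.666	101.398	98.165	93.958	93.233	96.326
gGDH1	91.525	108.017	86.701	103.542	83.069	111.942	88.033	97.459	100.102
gGDH2	116.711	105.59	95.457	93.594	115.206	85.44	94.901	95.669	93.811
gGDH3	102.835	109.079	95.654	102.954	101.038	105.59	93.516	96.368	104.933
gGLCT1	91.663	107.596	98.913	88.875	123.647	102.87	99.921	96.762	85.484
gGLCT2	104.471	100.246	111.071	114.832	104.347	110.662	90.838	104.542	102.599
gGLS	107.126	81.552	107.392	121.293	92.682	96.52	101.086	97.752	85.33
gGLY1	105.398	105.864	97.878	95.914	105.767	103.252	93.197	94.592	96.551
gGLY2	96.509	98.944	97.012	89.636	90.628	102.195	118.736	113.804	94.381
gICDH	115.74	97.963	106.684	105.335	87.778	94.247	106.894	97.389	93.22
gIDHm	103.457	85.892	105.197	98.166	102.444	112.276	108.983	97.731	98.937
gLDHA	93.508	94.856	92.879	126.511	95.187	111.744	103.398	98.509	82.165
gLDHB	79.734	103.748	92.705	99.112	99.512	106.718	117.729	106.851	111.925
gR1	111.348	113.982	103.196	106.606	100.244	116.612	93.372	98.772	84.24
gR2	99.055	98.484	107.45	199.561	187.61	210.433	380.049	396.51	379.977
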