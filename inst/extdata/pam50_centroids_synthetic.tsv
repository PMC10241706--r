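# SYNTHETIC PAM50 centroid fixture for subtypeAdmix.
# Gene symbols are the canonical PAM50 panel; centroid values are
# synthetic, structured after the subtypes' known marker biology
# (luminal ESR1/FOXA1 axis, proliferation cluster, HER2 amplicon,
# basal keratins). NOT the published centroid values; supply your own
# centroid table for real analyses.
gene	LumA	LumB	HER2	Basal	Normal
ACTR3B	-0.794	-0.752	-0.02	1.294	0
ANLN	-0.885	0.782	0.657	0.567	-0.95
BAG1	1.054	0.836	-0.65	-1.025	0.376
BCL2	1.095	0.696	-0.223	-1.241	0.509
BIRC5	-0.739	0.913	0.4	0.73	-1.207
BLVRA	0.984	0.641	-0.484	-1.386	0.027
CCNB1	-0.573	1.002	0.437	0.799	-1.106
CCNE1	-0.814	0.913	0.482	0.68	-1.158
CDC20	-0.497	0.451	0.528	0.72	-1.097
CDC6	-0.809	0.943	0.518	0.993	-1.028
CDH3	-0.804	-0.855	-0.204	1.274	0.12
CENPF	-0.457	0.928	0.516	0.639	-0.694
CEP55	-1.008	0.987	0.427	0.824	-0.984
CXXC5	0.958	0.81	-0.576	-1.254	0.187
EGFR	-1.02	-0.909	-0.449	1.389	0.374
ERBB2	-0.205	0.095	1.543	-0.185	-0.194
ESR1	0.957	0.65	-0.577	-1.349	0.18
EXO1	-1.198	1.056	0.905	0.868	-0.778
FGFR4	-0.666	0.038	1.396	-0.387	-0.233
FOXA1	1.198	0.708	-0.479	-1.066	0.007
FOXC1	-1.046	-0.956	-0.424	1.266	0.358
GPR160	0.733	0.586	-0.721	-1.075	0.147
GRB7	-0.326	-0.006	1.619	-0.662	-0.278
KIF2C	-0.618	0.757	0.351	1.053	-1.16
KRT14	-0.716	-0.881	-0.2	1.43	0.364
KRT17	-1.065	-0.713	-0.264	1.277	0.274
KRT5	-1.039	-0.685	-0.292	1.083	0.377
MAPT	0.736	0.67	-0.804	-1.104	0.165
MDM2	1.069	0.467	-0.684	-1.128	0.101
MELK	-0.896	0.735	0.527	0.799	-0.812
MIA	-0.932	-0.573	-0.115	1.323	0.259
MKI67	-0.694	0.939	0.426	0.712	-0.858
MLPH	1.155	0.613	-0.5	-1.145	0.02
MMP11	-0.391	-0.118	1.768	-0.356	-0.27
MYBL2	-0.724	0.721	0.716	0.758	-1.04
MYC	-1.258	-0.708	-0.365	1.1	0.241
NAT1	0.882	0.567	-0.518	-1.095	0.402
NDC80	-0.928	0.873	0.68	0.883	-1.003
NUF2	-1.162	1.04	0.43	0.675	-0.963
ORC6	-0.795	1.023	0.492	0.561	-1.141
PGR	1.031	0.809	-0.513	-1.169	0.091
PHGDH	-1.054	-0.871	-0.333	1.248	0.45
PTTG1	-0.686	0.998	0.433	0.838	-0.811
RRM2	-0.909	1.109	0.496	0.606	-0.813
SFRP1	-1.205	-0.967	-0.262	1.156	0.093
SLC39A6	1.065	0.471	-0.333	-1.037	0.507
TMEM45B	0.878	0.43	-0.572	-1.139	0.353
TYMS	-0.583	0.681	0.435	0.888	-1.004
UBE2C	-0.865	0.912	0.605	1.072	-0.894
UBE2T	-0.702	0.998	0.342	0.819	-1.146
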