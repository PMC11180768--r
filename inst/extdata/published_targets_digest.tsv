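outcome	protein	snp	or_	ci_low	ci_high	pvalue	steiger_pvalue	steiger_flag	bidir_or	bidir_pvalue	bidir_flag	phenoscan_flag	pph4	coloc_flag	rep_sig_pvalue	rep_sig_flag	rep_same_pvalue	rep_same_flag	verdict_printed
BC_overall	TLR1	rs5743618	1.18	1.13	1.24	2.83E-12	1.07E-46	Passed	1.025	0.216	Passed	Passed	0.977	Passed	2.83E-12	Passed	2.83E-12	Passed	YES
BC_overall	PDCD6	rs56075848	1.34	1.20	1.50	2.03E-07	2.94E-09	Passed	1.005	0.673	Passed	Passed	3.283E-04	NO	1.39E-05	Passed	2.03E-07	Passed	NO
BC_overall	RCL	rs114371775	1.21	1.12	1.30	4.46E-07	9.10E-21	Passed	1.011	0.383	Passed	Passed	0.562	NO	3.47E-05	Passed	NA	*	NO
BC_overall	A4GALT	rs8138197	0.93	0.90	0.96	3.97E-06	7.83E-104	Passed	0.992	0.482	Passed	Passed	0.960	Passed	3.40E-06	Passed	3.97E-06	Passed	YES
BC_overall	PARK7	rs17523802	0.95	0.93	0.97	4.69E-06	2.18E-188	Passed	1.011	0.353	Passed	Passed	0.698	NO	0.0168	NO	4.69E-06	Passed	NO
BC_overall	SNUPN	rs7170787	0.91	0.88	0.95	5.78E-06	1.01E-71	Passed	0.994	0.606	Passed	Passed	0.729	Passed	1.23E-05	Passed	5.78E-06	Passed	YES
BC_overall	CTSF	rs1044522	1.11	1.06	1.17	1.03E-05	4.81E-47	Passed	1.008	0.548	Passed	Passed	0.916	Passed	7.53E-06	Passed	1.03E-05	Passed	YES
BC_overall	GCDH	rs2238641	0.84	0.78	0.91	1.28E-05	6.56E-20	Passed	NA	NA	Lack of data	Passed	NA	NA	NA	Lack of data	NA	Lack of data	NO
BC_overall	SEMA4A	rs12401997	1.11	1.06	1.17	1.37E-05	1.54E-50	Passed	1.007	0.585	Passed	Passed	0.116	NO	2.21E-05	Passed	1.37E-05	Passed	NO
BC_overall	LAYN	rs4938792	1.11	1.06	1.17	1.70E-05	3.26E-44	Passed	1.014	0.268	Passed	Passed	0.512	NO	1.70E-05	Passed	1.70E-05	Passed	NO
BC_overall	HAPLN4	rs55762233	1.14	1.07	1.20	2.14E-05	9.37E-30	Passed	1.011	0.438	Passed	Passed	2.120E-05	NO	1.00E-05	Passed	2.14E-05	Passed	NO
BC_ER+	TLR1	rs5743618	1.19	1.12	1.25	2.65E-09	3.74E-46	Passed	1.028	0.232	Passed	Passed	0.948	Passed	2.65E-09	Passed	2.65E-09	Passed	YES
BC_ER+	GDI2	rs55913768	0.92	0.90	0.96	2.24E-06	2.89E-150	Passed	1.006	0.583	Passed	Passed	0.789	NO	NA	Lack of data	2.24E-06	Passed	NO
BC_ER-	MST1	rs3197999	1.06	1.04	1.09	3.98E-07	1.89E-178	Passed	0.995	0.688	Passed	NO	0.958	Passed	1.23E-06	Passed	3.98E-07	Passed	NO
BC_ER-	GPX1	rs9823546	1.45	1.25	1.69	1.09E-06	1.87E-14	Passed	0.996	0.801	Passed	NO	0.282	NO	NA	Lack of data	1.09E-06	Passed	NO
BC_ER-	KDELC2	rs141379009	1.15	1.08	1.22	2.60E-06	7.52E-168	Passed	0.999	0.971	Passed	Passed	0.652	NO	2.29E-06	Passed	2.60E-06	Passed	NO
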