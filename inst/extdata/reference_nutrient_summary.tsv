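nutrient	unit	mean_a	sd_a	median_a	q25_a	q75_a	mean_b	sd_b	median_b	q25_b	q75_b	p_printed	spearman_rho
energy	kcal	2112	795	1994	1534	2488	2100	675	1994	1614	2539	.59	0.75
fat	g	83	42	76	51	105	88	39	81	61	110	.001	0.74
saturated_fatty_acids	g	29	15	27	18	38	31	15	28	20	39	.01	0.70
protein	g	82	34	77	59	100	82	30	77	62	101	.54	0.70
vegetable_protein	g	33	15	30	23	41	33	13	30	23	42	.37	0.75
carbohydrates	g	230	99	215	166	280	215	77	208	160	259	.04	0.78
mono_and_disaccharides	g	93	53	81	56	120	85	43	80	56	111	.01	0.80
fiber	g	21	11	20	14	26	21	9	20	14	26	.15	0.75
alcohol	g	10	21	0	0	11	9	20	0	0	10	.45	0.92
water	g	2681	1012	2570	2048	3229	2907	955	2775	2285	3349	<.001	0.68
vitamin_a	ug_rae	714	1007	453	286	685	804	1013	515	334	806	<.001	0.74
vitamin_b1	mg	1.0	0.6	0.9	0.7	1.3	1.0	0.5	0.9	0.7	1.3	.21	0.63
vitamin_b2	mg	1.3	0.6	1.3	0.9	1.6	1.4	0.6	1.3	1.0	1.8	.002	0.73
vitamin_b3	mg	18.8	10.8	16.5	10.8	24.4	19.0	9.3	17.3	11.5	24.4	.17	0.70
vitamin_b6	mg	1.5	0.7	1.4	1.0	1.9	1.6	0.7	1.5	1.1	1.9	<.001	0.71
folate_equivalents	ug	266	148	241	172	331	286	122	269	203	357	<.001	0.67
vitamin_b12	ug	3.8	3.2	2.9	2.0	4.8	4.2	3.4	3.2	2.2	5.1	.001	0.78
vitamin_c	mg	94	123	65	32	108	88	74	67	33	128	.09	0.77
vitamin_d	ug	2.3	2.2	1.8	0.9	2.9	2.7	2.5	2.1	1.2	3.5	<.001	0.64
vitamin_e	mg	11.4	7.3	9.7	6.5	14.3	13.1	6.7	11.7	8.2	16.7	<.001	0.58
calcium	mg	965	451	909	658	1231	1006	452	921	664	1295	.12	0.74
iodine	ug	173	92	159	111	213	172	79	162	116	209	.42	0.80
iron	mg	10.3	4.5	9.3	7.2	12.7	10.2	4.0	9.4	7.2	12.1	.41	0.73
magnesium	mg	338	126	334	249	403	346	118	328	264	411	.04	0.72
phosphorus	mg	1504	537	1466	1086	1864	1506	489	1478	1135	1790	.63	0.72
potassium	mg	3202	1202	3147	2314	3860	3206	1059	3106	2475	3886	.38	0.72
selenium	ug	52	44	43	31	58	50	32	43	31	63	.60	0.68
sodium	mg	2625	1443	2373	1637	3096	2410	1040	2283	1694	2875	.05	0.55
zinc	mg	10.1	4.5	9.4	7.0	12.5	10.3	3.9	10.0	7.5	12.3	.10	0.70
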