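variable	mean_a	sd_a	median_a	q25_a	q75_a	mean_b	sd_b	median_b	q25_b	q75_b	p_printed	spearman_rho
vegetables	163	200	117	31	226	160	144	130	50	240	.13	0.76
fruit	128	186	83	0	188	140	146	130	0	217	.005	0.79
added_fats	16	16	12	3	24	19	15	17	6	29	.001	0.54
meat	103	112	73	23	135	92	83	75	33	120	.10	0.70
eggs	17	37	0	0	0	17	34	0	0	13	.44	0.76
nuts	15	30	0	0	20	15	30	0	0	20	.73	0.84
milk_and_milk_products	264	263	219	16	391	288	248	252	80	423	.02	0.80
cheese	33	36	30	0	56	39	44	31	0	62	.006	0.76
bread	146	113	126	70	199	138	88	132	70	180	.95	0.85
cereal_products	67	133	6	0	88	74	106	20	0	119	.01	0.80
potatoes	72	119	0	0	128	66	104	0	0	120	.96	0.88
drinks	1888	956	1836	1275	2311	2097	889	1963	1582	2539	<.001	0.68
sandwich_spreads	15	27	0	0	20	12	23	0	0	15	.05	0.88
snacks	91	119	52	15	118	83	89	56	14	126	.41	0.88
sauces	21	37	2	0	26	33	38	22	0	57	<.001	0.60
other	13	52	0	0	10	5	12	0	0	5	<.001	0.50
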