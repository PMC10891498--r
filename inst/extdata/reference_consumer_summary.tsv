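variable	consumers_a	median_consumers_a	consumers_b	median_consumers_b	mcnemar_p_printed	wilcoxon_p_printed
vegetables	175	146	181	147	.16	.23
fruit	134	156	148	165	.002	.21
added_fats	173	15	186	20	.02	.06
fish	25	90	26	115	.66	.04
legumes	5	111	10	79	.06	.38
meat	178	86	179	85	.81	.06
eggs	52	50	61	50	.08	.83
nuts	66	32	70	31	.32	.29
milk_and_milk_products	165	265	173	302	.06	.13
cheese	138	36	145	45	.11	.03
bread	194	136	198	140	.10	.71
cereal_products	113	70	124	98	.03	.05
potatoes	87	150	90	142	.44	.91
drinks	206	1848	211	1963	NA	<.001
sandwich_spreads	85	26	89	20	.25	.01
soups	33	188	28	50	.10	<.001
snacks	173	72	172	78	.76	.69
sauces	116	24	143	45	<.001	.004
other	126	5	59	12	<.001	.11
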