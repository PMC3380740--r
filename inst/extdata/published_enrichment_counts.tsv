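source	gene	HM	HN	CM	CN	O_hc_printed	p_printed
JASPAR	KLF4	886	8988	643.15	9230.85	1.415	<0.0001
JASPAR	ZFX	437	9437	329	9545	1.343	<0.0001
JASPAR	CTCF	1002	8872	769.9	9104.1	1.336	<0.0001
JASPAR	PRDM9	1405	8469	1120.35	8753.65	1.30	<0.0001
JASPAR	RXRA	1015	8859	819.55	9054.45	1.266	<0.0001
JASPAR	ESRRB	792	9082	663.4	9210.6	1.211	0.0002
JASPAR	GABPA	110	9764	67.05	9806.95	1.648	0.0006
JASPAR	MYCN	197	9677	137.45	9736.55	1.440	0.0006
JASPAR	SPZ1	322	9552	249.55	9624.45	1.300	0.0013
JASPAR	MYC	129	9745	91	9783	1.423	0.0061
JASPAR	PAX5	194	9680	151.35	9722.65	1.287	0.0113
JASPAR	EGR1	85	9789	61.55	9812.45	1.384	0.0343
JASPAR	T	189	9685	155.95	9718.05	1.216	0.0411
TRANSFAC	MYOD1	483	9391	341.05	9532.95	1.434	<0.0001
TRANSFAC	MYC/MAX	98	9776	58.25	9815.75	1.689	0.0009
TRANSFAC	USF2	111	9763	70.05	9803.95	1.591	0.0014
TRANSFAC	ATF4	79	9795	44.55	9829.45	1.780	0.0015
TRANSFAC	USF1	101	9773	63.45	9810.55	1.598	0.0019
TRANSFAC	AHR	97	9777	62.3	9811.7	1.563	0.0034
TRANSFAC	ARNT	91	9783	60.2	9813.8	1.516	0.0071
TRANSFAC	ETS1	64	9810	40.95	9833.05	1.567	0.0157
TRANSFAC	ATF4_2	67	9807	44.35	9829.65	1.514	0.0181
TRANSFAC	CNTN2	43	9831	27.6	9846.4	1.56	0.0480
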