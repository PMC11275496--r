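region	a_pct	c_pct	g_pct	t_pct	at_pct	gc_pct	at_skew	gc_skew
whole_genome	30.06	31.45	14.78	23.71	53.77	46.23	0.12	-0.36
rrnS	31.22	26.94	21.12	20.71	51.94	48.06	0.20	-0.12
rrnL	34.39	23.94	20.39	21.28	55.67	44.33	0.24	-0.08
nad1	26.67	32.75	14.52	26.06	52.73	47.27	0.01	-0.39
nad2	30.74	34.1	10.85	24.3	55.04	44.96	0.12	-0.52
cox1	27.79	30.5	17.15	24.56	52.35	47.65	0.06	-0.28
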