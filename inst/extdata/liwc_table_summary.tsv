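category	family	t_printed	df_printed	p_printed	mean_eastern	sd_eastern	n_eastern	mean_western	sd_western	n_western
emo_pos	affective	8.36	38680	<.001	0.81	3.96	21156	0.52	3.04	21156
emo_neg	affective	2.55	41417	.01	29.68	20.76	21156	29.17	20.40	21156
emo_anx	affective	-0.89	41161	.38	0.08	1.22	21156	0.09	1.34	21156
emo_anger	affective	1.68	41336	.09	0.75	4.44	21156	0.68	4.26	21156
emo_sad	affective	2.48	41402	.01	28.61	21.32	21156	28.10	20.83	21156
swear	affective	-8.17	35782	<.001	0.19	2.15	21156	0.41	3.31	21156
physical	biological	-17.16	38642	<.001	2.41	9.15	21156	4.22	12.19	21156
health	biological	-14.52	38743	<.001	2.03	8.78	21156	3.50	11.64	21156
mental	biological	-14.48	38665	<.001	1.94	8.68	21156	3.39	11.56	21156
sexual	biological	-5.83	34934	<.001	0.05	0.94	21156	0.12	1.51	21156
death	biological	-4.52	39108	<.001	0.08	1.13	21156	0.14	1.47	21156
family	social	-1.20	41369	.23	0.23	2.17	21156	0.26	2.29	21156
friend	social	-2.20	41275	.03	0.18	1.61	21156	0.22	1.75	21156
home	social	-4.00	36882	<.001	0.03	0.64	21156	0.06	0.93	21156
work	social	-2.19	39489	.03	0.09	1.07	21156	0.11	1.35	21156
past_focus	time	-8.55	40306	<.001	0.86	4.01	21156	1.24	4.81	21156
present_focus	time	36.25	41120	<.001	19.45	18.67	21156	13.05	17.25	21156
future_focus	time	-0.51	41424	.61	0.39	2.53	21156	0.40	2.50	21156
visual	perceptual	-6.21	36391	<.001	0.13	1.53	21156	0.25	2.29	21156
auditory	perceptual	1.42	41360	.16	0.19	2.08	21156	0.16	2.01	21156
feel	perceptual	6.21	40875	<.001	1.86	6.48	21156	1.48	5.82	21156
pron_1st	pronoun	3.11	41085	.002	20.61	18.49	21156	20.06	17.00	21156
pron_2nd	pronoun	-5.60	41233	<.001	3.43	8.15	21156	3.90	8.86	21156
pron_3rd	pronoun	0.13	41441	.90	0.26	1.97	21156	0.26	1.96	21156
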