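region	family	n_reference	x_used	printed_inferior	printed_superior	printed_margin	printed_category
ES	TOTAL	2258	207	0.080	0.104		total
ES	Araceae	13	7	0.289	0.770	0.184	overused
ES	Zingiberaceae	14	6	0.213	0.677	0.108	overused
ES	Marantaceae	3	2	0.194	0.932	0.090	overused
ES	Solanaceae	9	4	0.187	0.738	0.083	overused
ES	Euphorbiaceae	83	22	0.182	0.369	0.078	overused
ES	Convolvulaceae	13	5	0.177	0.649	0.072	overused
ES	Datiscaceae	1	1	0.158	0.987	0.054	overused
ES	Fabaceae	82	19	0.154	0.334	0.050	overused
ES	Gnetaceae	4	2	0.147	0.853	0.042	overused
ES	Davalliaceae	8	3	0.137	0.701	0.033	overused
ES	Lamiaceae	42	10	0.135	0.386	0.031	overused
ES	Anacardiaceae	18	5	0.126	0.512	0.021	overused
ES	Asteraceae	19	5	0.119	0.491	0.015	overused
ES	Menispermaceae	15	4	0.110	0.524	0.006	overused
ES	Piperaceae	15	4	0.110	0.524	0.006	overused
ES	Poaceae	106	3	0.010	0.080	0.028	underused
EH	TOTAL	3549	156	0.038	0.051		total
EH	Ebenaceae	2	2	0.292	0.992	0.241	overused
EH	Winteraceae	2	2	0.292	0.992	0.241	overused
EH	Acanthaceae	12	5	0.192	0.684	0.141	overused
EH	Hypoxidaceae	1	1	0.158	0.987	0.107	overused
EH	Smilacaceae	7	3	0.157	0.755	0.106	overused
EH	Plantaginaceae	5	2	0.118	0.777	0.067	overused
EH	Lamiaceae	21	5	0.107	0.454	0.056	overused
EH	Araliaceae	17	4	0.097	0.476	0.046	overused
EH	Commelinaceae	2	1	0.094	0.906	0.043	overused
EH	Elaeagnaceae	2	1	0.094	0.906	0.043	overused
EH	Actinidiaceae	14	3	0.078	0.481	0.027	overused
EH	Asteraceae	103	13	0.076	0.204	0.024	overused
EH	Bignoniaceae	3	1	0.068	0.806	0.016	overused
EH	Casuarinaceae	3	1	0.068	0.806	0.016	overused
EH	Lecythidaceae	3	1	0.068	0.806	0.016	overused
EH	Symplocaceae	3	1	0.068	0.806	0.016	overused
EH	Onagraceae	9	2	0.067	0.556	0.016	overused
EH	Theaceae	9	2	0.067	0.556	0.016	overused
EH	Begoniaceae	10	2	0.060	0.518	0.009	overused
EH	Balsaminaceae	4	1	0.053	0.716	0.002	overused
EH	Caprifoliaceae	4	1	0.053	0.716	0.002	overused
EH	Icacinaceae	4	1	0.053	0.716	0.002	overused
EH	Oxalidaceae	4	1	0.053	0.716	0.002	overused
EH	Selaginellaceae	4	1	0.053	0.716	0.002	overused
EH	Usneaceae	4	1	0.053	0.716	0.002	overused
EH	Orchidaceae	191	1	0.001	0.029	-0.009	underused
BV	TOTAL	1524	154	0.087	0.117		total
BV	Verbenaceae	3	3	0.398	0.994	0.280	overused
BV	Musaceae	2	2	0.292	0.992	0.175	overused
BV	Zingiberaceae	19	9	0.272	0.685	0.155	overused
BV	Gnetaceae	3	2	0.194	0.932	0.077	overused
BV	Arecaceae	19	7	0.191	0.592	0.074	overused
BV	Marattiaceae	6	3	0.184	0.816	0.067	overused
BV	Caricaceae	1	1	0.158	0.987	0.041	overused
BV	Xanthorrhoeaceae	1	1	0.158	0.987	0.041	overused
BV	Leeaceae	4	2	0.147	0.853	0.029	overused
BV	Fabaceae	53	12	0.135	0.356	0.018	overused
BV	Thelypteridaceae	9	3	0.122	0.652	0.004	overused
BV	Malvaceae	30	7	0.119	0.411	0.001	overused
BV	Orchidaceae	74	1	0.003	0.072	-0.015	underused
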