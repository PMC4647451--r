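region	family	n_reference	x_used	printed_inferior	printed_superior	printed_margin	printed_category
ES	TOTAL	1176	203	0.152	0.195		total
ES	Convolvulaceae	6	5	0.421	0.963	0.226	overused
ES	Arecaceae	10	7	0.390	0.891	0.195	overused
ES	Marantaceae	2	2	0.292	0.992	0.097	overused
ES	Apocynaceae	25	9	0.202	0.557	0.007	overused
ES	Verbenaceae	22	0	0.001	0.148	-0.004	underused
EH	TOTAL	1176	147	0.107	0.145		total
EH	Monimiaceae	2	2	0.292	0.992	0.147	overused
EH	Plantaginaceae	2	2	0.292	0.992	0.147	overused
EH	Winteraceae	2	2	0.292	0.992	0.147	overused
EH	Melastomataceae	7	4	0.245	0.843	0.100	overused
EH	Asparagaceae	5	3	0.223	0.882	0.078	overused
EH	Smilacaceae	5	3	0.223	0.882	0.078	overused
EH	Onagraceae	3	2	0.194	0.932	0.049	overused
EH	Pittosporaceae	3	2	0.194	0.932	0.049	overused
EH	Asteraceae	47	13	0.170	0.418	0.024	overused
EH	Phyllanthaceae	1	1	0.158	0.987	0.013	overused
EH	Caryophyllaceae	1	1	0.158	0.987	0.013	overused
EH	Chloranthoceae	1	1	0.158	0.987	0.013	overused
EH	Elaegnaceae	1	1	0.158	0.987	0.013	overused
EH	Oleaceae	1	1	0.158	0.987	0.013	overused
EH	Polygalaceae	1	1	0.158	0.987	0.013	overused
EH	Tiliaceae	1	1	0.158	0.987	0.013	overused
EH	Proteaceae	4	2	0.147	0.853	0.001	overused
EH	Euphorbiaceae	88	3	0.012	0.095	-0.012	underused
BV	TOTAL	1177	146	0.106	0.144		total
BV	Arecaceae	10	7	0.390	0.891	0.246	overused
BV	Leeaceae	2	2	0.292	0.992	0.148	overused
BV	Rhizophoraceae	2	2	0.292	0.992	0.148	overused
BV	Thelypteridaceae	5	3	0.223	0.882	0.079	overused
BV	Zingiberaceae	23	9	0.221	0.594	0.077	overused
BV	Malvaceae	17	7	0.215	0.643	0.071	overused
BV	Salicaceae	1	1	0.158	0.987	0.014	overused
BV	Pteridaceae	1	1	0.158	0.987	0.014	overused
BV	Scrophulariaceae	1	1	0.158	0.987	0.014	overused
BV	Marattiaceae	7	3	0.157	0.755	0.013	overused
BV	Moraceae	38	10	0.150	0.421	0.006	overused
BV	Gnetaceae	4	2	0.147	0.853	0.003	overused
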