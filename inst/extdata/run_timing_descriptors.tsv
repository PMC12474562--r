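population	code	region	latitude	longitude	n_genetic	n_runtiming	n_years	early_doy	se_early	late_doy	se_late
English River	ENG	Labrador	54.966667	-59.75	27	4320	23	188	0.15	257	0.19
Campbellton River	CMP	Newfoundland	49.268516	-54.929383	25	6039	28	163	0.07	242	0.13
Western Arm Brook	WAB	Newfoundland	51.19	-56.768333	18	6786	28	172	0.10	239	0.14
Conne River	CNR	Newfoundland	47.923333	-55.683333	30	7220	28	146	0.10	210	0.14
Northeast Placentia River	NPR	Newfoundland	47.285	-53.793333	30	3369	15	178	0.15	234	0.21
Sand Hill	SH	Labrador	53.559196	-56.367329	19	4738	20	169	0.12	241	0.16
Terra Nova River	TNR	Newfoundland	48.545	-54.18	29	7327	27	167	0.10	246	0.15
Miramichi Southwest	MSW	Maritimes	46.881667	-65.66	23	7401	27	159	0.08	288	0.06
Upsalquitch	UPS	Maritimes	47.57175	-66.5354	28	4786	22	180	0.11	276	0.17
Nashwaak	NSH	Maritimes	46.118333	-66.613333	44	5875	24	159	0.17	283	0.20
Miramichi Upper Northwest	MUN	Maritimes	46.936667	-65.778333	24	6995	23	169	0.26	286	0.06
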