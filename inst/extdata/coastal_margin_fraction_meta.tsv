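sample_id	size_fraction	habitat	post_qc_reads	chl_a	phaeophytin_a	poc	pon	salinity	oxygen
GS310	0.1	hypoxic	530848	5.15	1.83	237.5	43.1	33.93	0.7
GS310	0.8	hypoxic	246287	5.15	1.83	237.5	43.1	33.93	0.7
GS310	3.0	hypoxic	225654	5.15	1.83	237.5	43.1	33.93	0.7
GS311	0.1	deep	561066	0	0	44.7	3	34.45	0.61
GS311	0.8	deep	287577	0	0	44.7	3	34.45	0.61
GS311	3.0	deep	512566	0	0	44.7	3	34.45	0.61
GS312	0.1	plume	478603	14.72	0.32	415.2	66	31.47	9.05
GS312	0.8	plume	219720	14.72	0.32	415.2	66	31.47	9.05
GS312	3.0	plume	198156	14.72	0.32	415.2	66	31.47	9.05
GS313	0.1	etm	484724	3.14	0.26	1667.5	215	19.05	6.56
GS313	0.8	etm	130255	3.14	0.26	1667.5	215	19.05	6.56
GS313	3.0	etm	185969	3.14	0.26	1667.5	215	19.05	6.56
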