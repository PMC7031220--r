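site_id	site_name	lake_area_km2	watershed_area_km2	peak_thg_ng_g	latitude	longitude
HAR	Kokemaenjoki/Harjavalta	NA	26100	2739	61.33207	22.12895
POK	Pocket Lake	0.048	0.095	1906	62.50897	-114.37377
OJA	Ojanjarvi	12	3970	1057	63.80657	22.99994
PAI	Paivajarvi	0.13	0.95	415	63.88923	23.24727
AQT	Aquatuk Lake	8.28	231	110	54.3281	-84.5686
PUL	Pulmankijarvi	11.2	800	126	69.97459	28.00415
KEV	Kevojarvi	1.1	1470	91	69.75804	26.99785
LAH	Lake Hazen	540	6860	63	81.8245	-70.71604
VUO	Vuolimus Cieskuljavri	0.39	22.5	50	69.73197	27.09612
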