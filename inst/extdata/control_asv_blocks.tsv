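dataset	asv_id	taxon	control	gut	urt	lrt
Aedes	Aedes_Enterobacter_1	Enterobacter	40.06	25.89	16.73	22.48
Aedes	Aedes_Enterobacter_2	Enterobacter	19.64	13.05	6.27	8.33
Aedes	Aedes_Serratia_1	Serratia	5.69	10.16	2.93	3.23
Aedes	Aedes_Cutibacterium_1	Cutibacterium	1.11	0	0	0
Aegypti	Aegypti_Serratia_1	Serratia	6.34	0	NA	NA
Aegypti	Aegypti_Halomonas_1	Halomonas	5.22	0	NA	NA
Aegypti	Aegypti_Halomonas_2	Halomonas	4.54	0	NA	NA
Aegypti	Aegypti_Serratia_2	Serratia	3.79	0	NA	NA
Aegypti	Aegypti_Serratia_3	Serratia	2.18	0	NA	NA
Aegypti	Aegypti_Serratia_4	Serratia	2.16	0	NA	NA
Aegypti	Aegypti_Halomonas_3	Halomonas	2.14	0	NA	NA
Aegypti	Aegypti_Halomonas_4	Halomonas	2.06	0	NA	NA
Aegypti	Aegypti_Halomonas_5	Halomonas	1.78	0	NA	NA
Aegypti	Aegypti_Halomonas_6	Halomonas	1.67	0	NA	NA
Aegypti	Aegypti_Vibrio_1	Vibrio	1.24	0	NA	NA
Aegypti	Aegypti_Marinimicrobium_1	Marinimicrobium	1.16	0	NA	NA
Aegypti	Aegypti_Serratia_5	Serratia	1.15	0	NA	NA
Aegypti	Aegypti_Serratia_6	Serratia	1.08	0	NA	NA
Aegypti	Aegypti_Halomonas_7	Halomonas	1.06	0	NA	NA
Aegypti	Aegypti_Halomonas_8	Halomonas	1.06	0	NA	NA
Albopictus	Albopictus_Pseudomonas_1	Pseudomonas	60.64	2.76	NA	NA
Albopictus	Albopictus_Chryseobacterium_1	Chryseobacterium	4.82	2.66	NA	NA
Albopictus	Albopictus_Janthinobacterium_1	Janthinobacterium	3.24	1.72	NA	NA
Albopictus	Albopictus_Pseudomonas_2	Pseudomonas	2.89	0.25	NA	NA
Albopictus	Albopictus_Pseudomonas_3	Pseudomonas	2.07	0.07	NA	NA
Albopictus	Albopictus_Acinetobacter_1	Acinetobacter	1.53	0.03	NA	NA
Albopictus	Albopictus_Janthinobacterium_2	Janthinobacterium	1.08	0.5	NA	NA
Anopheles1	Anopheles1_Aeromonas_1	Aeromonas	17.74	9.93	NA	NA
Anopheles1	Anopheles1_Pantoea_1	Pantoea	12.38	8.75	NA	NA
Anopheles1	Anopheles1_Chryseobacterium_1	Chryseobacterium	9.14	1.74	NA	NA
Anopheles1	Anopheles1_Acinetobacter_1	Acinetobacter	6.36	2.36	NA	NA
Anopheles1	Anopheles1_Acinetobacter_2	Acinetobacter	3.55	5.31	NA	NA
Anopheles1	Anopheles1_Serratia_1	Serratia	3.53	5.04	NA	NA
Anopheles1	Anopheles1_Stenotrophomonas_1	Stenotrophomonas	3.26	1.61	NA	NA
Anopheles1	Anopheles1_Enhydrobacter_1	Enhydrobacter	1.82	3.16	NA	NA
Anopheles1	Anopheles1_Thorsellia_1	Thorsellia	1.54	3.06	NA	NA
Anopheles1	Anopheles1_Enhydrobacter_2	Enhydrobacter	1.38	0.23	NA	NA
Anopheles1	Anopheles1_Pseudomonas_1	Pseudomonas	1.36	1.4	NA	NA
Anopheles1	Anopheles1_Acinetobacter_3	Acinetobacter	1.17	0.11	NA	NA
Anopheles2	Anopheles2_Sphingomonas_1	Sphingomonas	35.85	0.01	0.0038	0.00121
Anopheles2	Anopheles2_Acinetobacter_1	Acinetobacter	21.94	4.36	5.74	5.01
Anopheles2	Anopheles2_Caulobacter_1	Caulobacter	19.83	0	0	0
Anopheles2	Anopheles2_Escherichia-Shigella_1	Escherichia-Shigella	8.26	2.09	2.23	2.27
Anopheles2	Anopheles2_Cloacibacterium_1	Cloacibacterium	4.46	0.86	1.02	0.99
Anopheles2	Anopheles2_Acinetobacter_2	Acinetobacter	1.67	0.14	0.11	0.14
Anopheles2	Anopheles2_Diaphorobacter_1	Diaphorobacter	1.08	0.18	0.22	0.21
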