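# Classification and characterisation table of the same published survey
# (transcribed): one row per element; copy counts, counts of copies with
# full LTRs / gag / pol / env, and representative lengths (consensus, LTR,
# protein lengths in aa; NA where the layout lacks the protein).
family	element	copies	full_ltr	gag_n	pol_n	env_n	consensus_bp	ltr_bp	gag_aa	pol_aa	gagpol_aa	env_aa
Gmr	Gmr1	20	16	19	20	0	6465	518	NA	NA	1634	NA
Gmr	Gmr2	6	6	4	6	0	6058	337	NA	NA	1564	NA
Gmr	Gmr3	11	10	9	11	0	6273	412	NA	NA	1506	NA
Gmr	Gmr4	10	9	8	10	0	6223	456	NA	NA	1521	NA
Mag	Mag1	20	18	20	19	0	4696	208	NA	NA	1365	NA
Mag	Mag2	4	4	4	4	0	4813	211	NA	NA	1330	NA
V-clade	V-clade1	55	47	47	55	0	5558	538	371	1119	NA	NA
V-clade	V-clade2	29	25	25	28	0	5226	443	329	890	NA	NA
V-clade	V-clade3	3	3	2	3	0	5346	497	326	822	NA	NA
V-clade	V-clade4	5	3	1	5	0	6444	454	309	1016	NA	NA
V-clade	V-clade5	12	9	11	12	0	5369	328	NA	NA	1281	NA
V-clade	V-clade6	4	3	1	4	0	5430	367	306	801	NA	NA
V-clade	V-clade7	4	4	3	4	0	5264	396	414	1119	NA	NA
CsRN1	CsRN1-1	21	21	0	21	0	4337	174	NA	1061	NA	NA
CsRN1	CsRN1-2	18	17	0	18	0	4552	302	NA	1069	NA	NA
Barthez	Barthez1	13	11	11	13	0	7871	1116	355	1394	NA	NA
Barthez	Barthez2	12	9	8	12	0	7566	1025	359	1339	NA	NA
Barthez	Barthez3	4	2	0	4	0	8756	1114	NA	1563	NA	NA
Barthez	Barthez4	5	5	0	5	0	7513	442	NA	1580	NA	NA
Barthez	Barthez5	17	7	9	17	0	7544	259	526	1580	NA	NA
Barthez	Barthez6	5	4	2	5	0	7310	329	879	1137	NA	NA
BEL-PAO	BEL1	3	3	0	3	0	7624	728	NA	1434	NA	NA
BEL-PAO	BEL2	7	5	0	7	0	6587	536	NA	1808	NA	NA
BEL-PAO	BEL3	10	9	0	9	0	7341	652	NA	1970	NA	NA
BEL-PAO	PAO1	4	3	0	3	0	5939	456	NA	1617	NA	NA
Copia	Copia1	4	4	2	4	0	4794	233	454	653	NA	NA
Orthoretrovirinae	Orthoretrovirinae1	3	3	0	3	0	8626	433	NA	1108	NA	NA
Epsilon retrovirus	Epsilon1	21	19	11	14	9	8630	665	728	776	NA	487
Epsilon retrovirus	Epsilon2	105	93	65	103	40	8158	382	219	951	NA	554
Epsilon retrovirus	Epsilon3	3	2	2	3	0	7880	470	576	740	NA	NA
Epsilon retrovirus	Epsilon4	5	2	4	5	2	9854	377	604	985	NA	477
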