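name	length	copy_number	cen_start	cen_end	gc_fraction
chr1	248956422	2	121700000	125100000	0.417
chr2	242193529	2	91800000	96000000	0.402
chr3	198295559	2	87800000	94000000	0.397
chr4	190214555	2	48200000	51800000	0.382
chr5	181538259	2	46100000	50100000	0.395
chr6	170805979	2	58500000	62300000	0.396
chr7	159345973	2	58100000	62400000	0.407
chr8	145138636	2	43200000	47200000	0.401
chr9	138394717	2	42200000	45500000	0.413
chr10	133797422	2	38000000	41600000	0.415
chr11	135086622	2	51000000	55800000	0.415
chr12	133275309	2	34700000	37200000	0.408
chr13	114364328	2	16500000	18900000	0.385
chr14	107043718	2	16100000	18200000	0.408
chr15	101991189	2	17500000	20500000	0.422
chr16	90338345	2	35300000	38300000	0.447
chr17	83257441	2	22700000	27400000	0.455
chr18	80373285	2	15400000	21000000	0.398
chr19	58617616	2	24200000	28100000	0.483
chr20	64444167	2	25700000	30400000	0.441
chr21	46709983	2	10900000	13000000	0.408
chr22	50818468	2	13700000	17400000	0.479
chrX	156040895	1	58100000	63800000	0.395
chrY	57227415	1	10300000	10600000	0.391
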