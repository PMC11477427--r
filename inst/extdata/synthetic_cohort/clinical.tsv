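sample_id	time	event	sex	age	stage
SIM-0001-01	234.2	1	male	53.8	ii
SIM-0002-01	29.1	1	male	48.9	i
SIM-0003-01	1310.9	1	male	58.3	iii_iv
SIM-0004-01	551.1	0	female	54	iii_iv
SIM-0005-01	1381.9	1	female	74.3	iii_iv
SIM-0006-01	1403	1	male	56.6	iii_iv
SIM-0007-01	229.9	0	male	74.2	ii
SIM-0008-01	1462.5	1	male	48.7	iii_iv
SIM-0009-01	42.3	0	female	57.4	i
SIM-0010-01	66.2	1	male	44.5	iii_iv
SIM-0011-01	2.1	0	female	57.8	ii
SIM-0012-01	422.4	1	female	74	i
SIM-0013-01	428.3	1	female	52.3	i
SIM-0014-01	955.7	1	female	69.6	ii
SIM-0015-01	275.6	1	male	54.6	ii
SIM-0016-01	854.6	1	male	71	iii_iv
SIM-0017-01	1448.8	1	female	55	i
SIM-0018-01	581.1	1	female	61.5	i
SIM-0019-01	110.6	0	male	56.8	ii
SIM-0020-01	1650.6	1	female	60.9	i
SIM-0021-01	283	0	male	57.4	iii_iv
SIM-0022-01	8.7	1	female	57.4	iii_iv
SIM-0023-01	1499.9	0	male	57.2	i
SIM-0024-01	181.1	1	female	77.4	i
SIM-0025-01	5.9	1	female	74.4	ii
SIM-0026-01	93.6	1	male	58.2	ii
SIM-0027-01	256.2	0	male	67.9	ii
SIM-0028-01	152.1	1	female	65.5	iii_iv
SIM-0029-01	1340.6	1	female	54.4	i
SIM-0030-01	283.5	1	female	55.6	iii_iv
SIM-0031-01	698.9	1	male	65.9	ii
SIM-0032-01	375.3	1	female	75.5	iii_iv
SIM-0033-01	137.1	1	male	61	ii
SIM-0034-01	819.1	1	male	53.8	ii
SIM-0035-01	75.6	1	male	63.1	i
SIM-0036-01	554.8	0	female	68.6	i
SIM-0037-01	57	1	male	63.7	ii
SIM-0038-01	1970.5	1	male	58.2	ii
SIM-0039-01	188.5	0	male	73	iii_iv
SIM-0040-01	647	1	female	57.1	iii_iv
SIM-0041-01	40.7	1	male	70.9	ii
SIM-0042-01	834.4	1	female	38.6	i
SIM-0043-01	129.9	1	female	65.9	ii
SIM-0044-01	403.4	1	male	64.8	ii
SIM-0045-01	36.5	1	female	58.5	ii
SIM-0046-01	1678.2	1	male	59.3	i
SIM-0047-01	600.3	1	male	69.3	ii
SIM-0048-01	367.1	1	female	70	ii
SIM-0049-01	1123.8	1	female	58	iii_iv
SIM-0050-01	1.2	0	female	56.7	ii
SIM-0051-01	863	1	male	60.2	i
SIM-0052-01	140.6	0	female	70.8	i
SIM-0053-01	840.9	1	male	56.8	i
SIM-0054-01	88.6	1	male	76.9	i
SIM-0055-01	431.9	1	male	66.3	i
SIM-0056-01	117.6	1	male	61.8	i
SIM-0057-01	137.8	1	male	61.2	iii_iv
SIM-0058-01	241.5	1	female	53.7	ii
SIM-0059-01	362	0	female	91.1	ii
SIM-0060-01	54.7	1	female	63.3	i
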