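family	gene_a	gene_b	similarity	correlation
MAPK	BdMPK3	OsMPK3	91.9	-0.113
MAPK	BdMPK4	OsMPK4	94.4	0.113
MAPK	BdMPK6	OsMPK6	94.5	0.594
MAPK	BdMPK14	OsMPK14	96.2	0.311
MAPK	BdMPK16	OsMPK16	81.3	-0.345
MAPK	BdMPK17	OsMPK17-1	86.5	-0.097
MAPK	BdMPK20-1	OsMPK20-1	90.4	0.276
MAPK	BdMPK20-3	OsMPK20-3	65.6	0.829
MAPK	BdMPK20-4	OsMPK20-4	86.8	-0.492
MAPK	BdMPK21-1	OsMPK21-1	81.9	0.075
MAPKK	BdMKK1	OsMKK1	87.2	-0.289
MAPKK	BdMKK3-1	BdMKK3-2	90.2	0.263
MAPKK	BdMKK4	OsMKK4	90.8	0.045
MAPKK	BdMKK5	OsMKK5	82.9	0.396
MAPKK	BdMKK6	OsMKK6	93.3	0.204
MAPKK	BdMKK10-2	OsMKK10-2	84.8	-0.066
MAPKK	BdMKK10-4	BdMKK10-5	69.9	0.657
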