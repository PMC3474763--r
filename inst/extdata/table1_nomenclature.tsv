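family	bd_name	bd_gene_model	at_name	at_code	os_name	os_code
MAPK	BdMPK3	Bradi1g65810	AtMPK1	At1g10210	OsMPK3	Os03g17700
MAPK	BdMPK4	Bradi3g32000	AtMPK2	At1g59580	OsMPK4	Os10g38950
MAPK	BdMPK6	Bradi1g49100	AtMPK3	At3g45640	OsMPK6	Os06g06090
MAPK	BdMPK7-1	Bradi1g34030	AtMPK4	At4g01370	OsMPK7	Os06g48590
MAPK	BdMPK7-2	Bradi4g24912	AtMPK5	At4g11330	OsMPK14	Os02g05480
MAPK	BdMPK11	Bradi3g16560	AtMPK6	At2g43790	OsMPK16	Os11g17080
MAPK	BdMPK14	Bradi3g03780	AtMPK7	At2g18170	OsMPK17-1	Os06g49430
MAPK	BdMPK16	Bradi2g36470	AtMPK8	At1g18150	OsMPK17-2	Os02g04230
MAPK	BdMPK17	Bradi1g34700	AtMPK9	At3g18040	OsMPK20-1	Os01g43910
MAPK	BdMPK20-1	Bradi2g44350	AtMPK10	At3g59790	OsMPK20-2	Os05g50560
MAPK	BdMPK20-2	Bradi2g15317	AtMPK11	At1g01560	OsMPK20-3	Os06g26340
MAPK	BdMPK20-3	Bradi1g41780	AtMPK12	At2g46070	OsMPK20-4	Os01g47530
MAPK	BdMPK20-4	Bradi2g45870	AtMPK13	At1g07880	OsMPK20-5	Os05g49140
MAPK	BdMPK20-5	Bradi2g16337	AtMPK14	At4g36450	OsMPK21-1	Os05g50120
MAPK	BdMPK21-1	Bradi2g15620	AtMPK15	At1g73670	OsMPK21-2	Os01g45620
MAPK	BdMPK21-2	Bradi2g45010	AtMPK16	At5g19010
MAPKK	BdMKK1	Bradi1g51000	AtMKK1	At4g26070	OsMKK1	Os06g05520
MAPKK	BdMKK3-1	Bradi4g39490	AtMKK2	At4g29810	OsMKK3	Os06g27890
MAPKK	BdMKK3-2	Bradi1g41860	AtMKK3	At5g40440	OsMKK4	Os02g54600
MAPKK	BdMKK3-3	Bradi3g11260	AtMKK4	At1g51660	OsMKK5	Os06g09180
MAPKK	BdMKK4	Bradi3g53650	AtMKK5	At3g21220	OsMKK6	Os01g32660
MAPKK	BdMKK5	Bradi1g46880	AtMKK6	At5g56580	OsMKK10-1	Os02g46760
MAPKK	BdMKK6	Bradi1g75150	AtMKK7	At1g18350	OsMKK10-2	Os03g12390
MAPKK	BdMKK10-1	Bradi1g11525	AtMKK8	At3g06230	OsMKK10-3	Os03g50550
MAPKK	BdMKK10-2	Bradi1g69400	AtMKK9	At1g73500
MAPKK	BdMKK10-3	Bradi1g10800	AtMKK10	At1g32320
MAPKK	BdMKK10-4	Bradi1g10770
MAPKK	BdMKK10-5	Bradi1g10790
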