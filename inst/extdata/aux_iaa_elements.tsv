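iaa_index	ortholog	gene_id	element	orientation	distance_from_aug	linker_unspecified	induction_assay	gene_family
1	IAA4	PGSC0003DMG400016317	GTCAActtGTCA	HtT	1546	FALSE	NA	AUX/IAA
2	IAA1	PGSC0003DMG400020139	NA	NA	NA	FALSE	NA	AUX/IAA
3	IAA1	PGSC0003DMT400049677	TTGACTTGAC	TtH	1394	FALSE	induced	AUX/IAA
4	IAA9	PGSC0003DMG400006393	NA	NA	NA	FALSE	uninduced	AUX/IAA
5	IAA13	PGSC0003DMG400029339	NA	NA	NA	FALSE	uninduced	AUX/IAA
6	IAA8	PGSC0003DMG400002550	TGACctaatTTGAC	TtH	2524	FALSE	NA	AUX/IAA
7	IAA17	PGSC0003DMG400016280	NA	NA	NA	FALSE	NA	AUX/IAA
8	IAA16	PGSC0003DMG402002635	NA	NA	NA	FALSE	NA	AUX/IAA
9	IAA16	PGSC0003DMG402019457	TGACttattgcTTGAC	TtH	1674	FALSE	NA	AUX/IAA
10	IAA16	PGSC0003DMG400005327	NA	NA	NA	FALSE	NA	AUX/IAA
11	IAA19	PGSC0003DMG400002636	NA	NA	NA	FALSE	NA	AUX/IAA
12	IAA3	PGSC0003DMG400013445	TTGACataacaaTTGAC	TtH	794	FALSE	NA	AUX/IAA
13	ARF9	PGSC0003DMG400005794	NA	NA	NA	FALSE	NA	AUX/IAA
14	IAA18/28	PGSC0003DMG400002608	GTCAtGTCAA	HtT	2091	FALSE	induced	AUX/IAA
15	ARF9	PGSC0003DMG400000118	TGACtctaagacatTTGAC	TtH	1873	FALSE	NA	AUX/IAA
16	IAA19	PGSC0003DMG400016512	GTCAcTTGAC	HtH	2233	FALSE	NA	AUX/IAA
17	IAA3	PGSC0003DMG400005338	GTCAtttagattTTGAC	HtH	1152	FALSE	NA	AUX/IAA
18	IAA29	PGSC0003DMG400020478	TTGACacatttgaTGAC	TtH	992	FALSE	NA	AUX/IAA
19	IAA29	PGSC0003DMG400030896	NA	NA	NA	FALSE	NA	AUX/IAA
20	IAA33	PGSC0003DMG400043142	NA	NA	NA	FALSE	NA	AUX/IAA
21	IAA29	PGSC0003DMG400013765	NA	NA	NA	FALSE	NA	AUX/IAA
22	IAA10	PGSC0003DMG400008586	GTCAAttaaTTGAC	HtH	712	FALSE	induced	AUX/IAA
23	IAA4	PGSC0003DMG400006108	NA	NA	NA	FALSE	NA	AUX/IAA
24	IAA14	PGSC0003DMG400006093	TGACaatacataagaaGTCAA	TtT	667	FALSE	induced	AUX/IAA
25	IAA12	PGSC0003DMG400001498	TTGACattTTGAC	TtH	2319	FALSE	NA	AUX/IAA
26	IAA27	PGSC0003DMG400000375	NA	NA	NA	FALSE	NA	AUX/IAA
27	ARF16	PGSC0003DMG400021560	GTCAANNNNNNNNNNNNNNNNNNNNGTCAA	HtT	2235	TRUE	NA	AUX/IAA
NA	StBEL5	PGSC0003DMG400005930	GTCAAtgcTTGAC	HtH	970	FALSE	NA	BEL1-like
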