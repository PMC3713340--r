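gene	element	n_reported	orientation	distance_nt	anchor	note
StBEL5	GTCAAtgcTTGAC	1	HtH	820	TSS	BEL5/POTH1-bound autoregulatory element
StPIN1	TTGACactgagtttttcgattGTCAA	2	TtT	1249	AUG	auxin efflux
StPIN1	TTGACctacatacaatctGTCAA	2	TtT	914	AUG	auxin efflux; gel-shift probe element
StPIN2	GTCActatGTCAA	1	HtT	1343	AUG	auxin efflux
StPIN4	TGACactttcaGTCA	1	TtT	486	AUG	auxin efflux
StGA2ox1	TTGACaaGTCA	2	TtT	1768	AUG	annotated as a double palindromic motif
YUCCA1a	TTGACcttaTTGAC	1	TtH	641	AUG	auxin synthesis
YUCCA1c	TGACTTGAC	1	TtH	651	AUG	auxin synthesis; no linker
IPT	TTGACaaGTCA	2	TtT	1408	AUG	cytokinin synthesis
IPT	GTCAAtgcaTGAC	2	HtH	568	AUG	cytokinin synthesis
LAX1	TTGACttttgatctTTGAC	1	TtH	922	AUG	auxin influx
LAX4	TTGACTGAC	1	TtH	2629	AUG	auxin influx; no linker; beyond the 2-kb criterion
ARF8	GTCAActccacaatGTCA	1	HtT	138	AUG	auxin response factor
AGL8	GTCAttttcttcaatttgtctcgcttgtGTCA	1	HtT	1990	TSS	MADS-box gene POTM1-1
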