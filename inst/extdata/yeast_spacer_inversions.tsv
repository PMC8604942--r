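gene	arm_len	spacer_len	strains	kind	frame_offset	aa_changes	parental_seq	derived_seq
PIM1	10	3	YJM339	spacer_inversion	1	S>G	CTCCAGAAGCtccGCTTCTGGAG	CTCCAGAAGCggaGCTTCTGGAG
REG2	16	5	YJM339	combined	1	K>D;S>F	ACAGCGCCCTTGTTCAaagtcTGAACTAGATCCCTGT	ACAGCGCCCTTGTTCAgacttTGAACAAGGGCGCTGT
SYG1	10	4	JAY291	spacer_inversion	1	Y>G;R>R	ATCCAGCTCCtaccGGAGCTGGAT	ATCCAGCTCCggtaGGAGCTGGAT
AYR1	10	4	UWOPS05_217_3;YJM269	spacer_inversion	2	P>P;D>S	CTAATTTACCtgatGGTAAATTAG	CTAATTTACCatcaGGTAAATTAG
SPO75	11	2	D273-10B;CEN.PK;Y55	spacer_inversion	2	L>K	TGCCCGACGATttATCGTCGGGCA	TGCCCGACGATaaATCGTCGGGCA
ICT1	10	2	D273-10B;SEY6210;YJM789	spacer_inversion	2	L>L;K>Q	TGCAGGGCCTgaAGGCCCTGCA	TGCAGGGCCTtcAGGCCCTGCA
YPS1	11	3	UWOPS05_217_3	spacer_inversion	0	S>S;S>K	CCATACTGTTCttcGAACAGTATGG	CCATACTGTTCgaaGAACAGTATGG
ECM30	10	2	W303	spacer_inversion	1	D>S	GGAGGACGCAgaTGCGTCCTCC	GGAGGACGCAtcTGCGTCCTCC
YBZ1	10	3	UWOPS05_217_3;Kyokai7;RedStar;CLIB215;L1528	spacer_inversion	1	F>E	TGTCAATGCCttcGGCATTGACA	TGTCAATGCCgaaGGCATTGACA
TAT2	11	3	SEY6210	spacer_inversion	2	E>F	TTGGATTTGTAgaaTACAAATCCAA	TTGGATTTGTAttcTACAAATCCAA
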