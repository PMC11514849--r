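gene	aa_length
TP53	393
APC	2843
KRAS	189
BRAF	766
PIK3CA	1068
SMAD4	552
FBXW7	707
TTN	34350
MUC16	14507
SYNE1	8797
OBSCN	7968
KMT2C	4911
BCL9	1426
ERBB3	1342
EP300	2414
FAT3	4589
CARD11	1154
MSH2	934
MSH6	1360
MLH1	756
PMS2	862
POLD1	1107
POLE	2286
DBN1	649
ACTN4	911
CTNNB1	781
FN1	2386
VIM	466
CDH1	882
MMP2	660
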