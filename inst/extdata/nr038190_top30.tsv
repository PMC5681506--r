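gene_symbol	p_value	r
TBX4	0.000101	0.891002
RAPGEF4	0.000101	0.891000
TTC28	0.000102	0.890780
SH2D1B	0.000102	0.890723
ITGA8	0.000102	0.890706
PIP5K1B	0.000102	0.890704
C1orf145	0.000102	0.890619
ANXA3	0.000103	0.890460
GIMAP1	0.000103	0.890407
FAM83A	0.000103	-0.890375
BDNF	0.000104	0.890349
PLEKHH2	0.000104	0.890150
FAM162B	0.000105	0.889993
PRKG2	0.000105	0.889954
CTDSP1	0.000106	0.889779
PIK3C3	0.000107	0.889654
PTPLAD2	0.000107	0.889621
SYNGR1	0.000107	0.889601
ZAK	0.000108	0.889386
APPBP2	0.000109	0.889201
SPATA13	0.000110	0.888938
CBFA2T3	0.000110	0.888911
SNX1	0.000110	0.888899
CCNDBP1	0.000111	0.888839
NHSL1	0.000112	0.888607
FIGF	0.000112	0.888513
WNT7A	0.000113	0.888409
KIDINS220	0.000113	0.888351
JPH4	0.000113	0.888299
F10	0.000115	0.887960
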