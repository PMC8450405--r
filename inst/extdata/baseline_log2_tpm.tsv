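gene	log2_tpm_mean
XYLT1	6.8836
XYLT2	6.0706
B4GALT7	1.7514
FAM20B	5.3735
B3GALT6	2.0733
B3GAT3	3.8422
PXYLP1	5.3549
EXTL2	4.7809
EXTL3	1.8996
EXT1	6.2459
EXT2	5.2087
CSGALNACT1	7.1816
CSGALNACT2	4.9373
CHSY1	7.9737
CHSY3	5.4754
CHPF	7.223
CHPF2	6.8906
DSE	4
DSEL	1.3773
NDST1	5.6473
NDST2	2.9427
NDST3	0.8754
NDST4	1.6245
GLCE	3.3744
HS2ST1	4.613
HS6ST1	6.275
HS6ST2	6.2681
HS6ST3	4.3838
HS3ST1	4.4238
HS3ST2	6.7221
HS3ST3A1	1.5766
HS3ST3B1	4.3689
HS3ST4	5.7762
HS3ST5	3.0411
HS3ST6	7.0381
CHST11	3.9613
CHST12	6.698
CHST13	4.1539
CHST14	3.2823
UST	1.912
CHST3	4
CHST15	3
B3GNT7	4.7593
CHST5	7.5485
CHST6	6.9974
B4GALT4	7.6047
CHST1	6.3386
HAS1	3.8526
HAS2	7.516
HAS3	7.7574
TMEM2	0.7878
HYAL1	4.6243
HYAL2	5.482
SPAM1	4.5997
SLC35B2	0.5868
SLC35B3	0.7847
SLC35B4	7.8581
SLC35A2	2.3774
PAPSS1	0.539
PAPSS2	4.0144
CANT1	2.5926
IMPAD1	7.5294
GOLPH3	2.1556
SPPL3	1.23
ZNF263	5.5305
KDM2B	2.3138
VCAN	6
DCN	8
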