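# Published recurrence table with per-gene variant/carrier counts.
# Counts for the two-case columns are implied by the column semantics
# (2 different variants / 1 shared variant in exactly 2 cases); the
# >2-cases column counts are transcribed verbatim. Summing n_variants
# gives 270, while the source text reports 272 prioritized variants;
# the discrepancy is in the source and is preserved, not resolved.
gene	category	n_variants	n_carriers	n_hom
AASS	two_cases_two_variants	2	2	0
ABCA10	two_cases_two_variants	2	2	0
ABCA4	two_cases_two_variants	2	2	0
ABL2	two_cases_two_variants	2	2	0
ADAMTS12	two_cases_two_variants	2	2	0
ANAPC11	two_cases_two_variants	2	2	0
ANK3	two_cases_two_variants	2	2	0
ANKRD40	two_cases_two_variants	2	2	0
ARHGEF18	two_cases_two_variants	2	2	0
ARID1B	two_cases_two_variants	2	2	0
ASH1L	two_cases_two_variants	2	2	0
ATAD2	two_cases_two_variants	2	2	0
ATP10B	two_cases_two_variants	2	2	0
BIN1	two_cases_two_variants	2	2	0
C10orf54	two_cases_two_variants	2	2	0
C12orf42	two_cases_two_variants	2	2	0
C14orf159	two_cases_two_variants	2	2	0
C17orf107	two_cases_two_variants	2	2	0
C6	two_cases_two_variants	2	2	0
C9orf84	two_cases_two_variants	2	2	0
CA9	two_cases_two_variants	2	2	0
CDC42BPG	two_cases_two_variants	2	2	0
CERKL	two_cases_two_variants	2	2	0
CHAMP1	two_cases_two_variants	2	2	0
CLCN2	two_cases_two_variants	2	2	0
CRYBA1	two_cases_two_variants	2	2	0
CTSE	two_cases_two_variants	2	2	0
CUL7	two_cases_two_variants	2	2	0
CYYR1	two_cases_two_variants	2	2	0
DAB2IP	two_cases_two_variants	2	2	0
DAW1	two_cases_two_variants	2	2	0
DHX34	two_cases_two_variants	2	2	0
DNAH10	two_cases_two_variants	2	2	0
DNAH12	two_cases_two_variants	2	2	0
DNAH6	two_cases_two_variants	2	2	0
DYSF	two_cases_two_variants	2	2	0
EFHB	two_cases_two_variants	2	2	0
EP400	two_cases_two_variants	2	2	0
ERCC5	two_cases_two_variants	2	2	0
FAT4	two_cases_two_variants	2	2	0
FBLN7	two_cases_two_variants	2	2	0
FLJ00418	two_cases_two_variants	2	2	0
GBP3	two_cases_two_variants	2	2	0
GPX4	two_cases_two_variants	2	2	0
HK3	two_cases_two_variants	2	2	0
HPS6	two_cases_two_variants	2	2	0
IGFN1	two_cases_two_variants	2	2	0
IGSF10	two_cases_two_variants	2	2	0
IGSF22	two_cases_two_variants	2	2	0
KLHL33	two_cases_two_variants	2	2	0
LLGL1	two_cases_two_variants	2	2	0
MEX3D	two_cases_two_variants	2	2	0
MKS1	two_cases_two_variants	2	2	0
MMP20	two_cases_two_variants	2	2	0
MSLNL	two_cases_two_variants	2	2	0
NOD2	two_cases_two_variants	2	2	0
NUP153	two_cases_two_variants	2	2	0
OPLAH	two_cases_two_variants	2	2	0
PACSIN2	two_cases_two_variants	2	2	0
PARD6B	two_cases_two_variants	2	2	0
PCDHAC1	two_cases_two_variants	2	2	0
PDE4DIP	two_cases_two_variants	2	2	0
PISD	two_cases_two_variants	2	2	0
PLA2G4D	two_cases_two_variants	2	2	0
PSD3	two_cases_two_variants	2	2	0
PTH1R	two_cases_two_variants	2	2	0
PYHIN1	two_cases_two_variants	2	2	0
R3HDML	two_cases_two_variants	2	2	0
RET	two_cases_two_variants	2	2	0
RMDN1	two_cases_two_variants	2	2	0
RNF157	two_cases_two_variants	2	2	0
RNF34	two_cases_two_variants	2	2	0
RTEL1	two_cases_two_variants	2	2	0
SCN9A	two_cases_two_variants	2	2	0
5-Sep	two_cases_two_variants	2	2	0
SH3BP2	two_cases_two_variants	2	2	0
SHROOM4	two_cases_two_variants	2	2	0
SIRT5	two_cases_two_variants	2	2	0
SLC26A9	two_cases_two_variants	2	2	0
SLC2A7	two_cases_two_variants	2	2	0
SLC34A3	two_cases_two_variants	2	2	0
SLC52A2	two_cases_two_variants	2	2	0
SPTBN5	two_cases_two_variants	2	2	0
SRCAP	two_cases_two_variants	2	2	0
TAF15	two_cases_two_variants	2	2	0
TENM4	two_cases_two_variants	2	2	0
TJP3	two_cases_two_variants	2	2	0
TMEM143	two_cases_two_variants	2	2	0
TNRC6B	two_cases_two_variants	2	2	0
TOPORS	two_cases_two_variants	2	2	0
TSFM	two_cases_two_variants	2	2	0
TTC14	two_cases_two_variants	2	2	0
ZNF34	two_cases_two_variants	2	2	0
ZNF646	two_cases_two_variants	2	2	0
ZNF729	two_cases_two_variants	2	2	0
ZSCAN32	two_cases_two_variants	2	2	0
ACADL	two_cases_one_variant	1	2	0
C1orf87	two_cases_one_variant	1	2	0
CD1A	two_cases_one_variant	1	2	0
CITED4	two_cases_one_variant	1	2	0
GBA	two_cases_one_variant	1	2	0
IQSEC3	two_cases_one_variant	1	2	0
NSMAF	two_cases_one_variant	1	2	0
PPP2R1B	two_cases_one_variant	1	2	0
SERPINB2	two_cases_one_variant	1	2	0
SPTBN1	two_cases_one_variant	1	2	0
SYDE1	two_cases_one_variant	1	2	0
TNFRSF25	two_cases_one_variant	1	2	0
TRAPPC2L	two_cases_one_variant	1	2	0
TRIM32	two_cases_one_variant	1	2	0
C8orf46	more_than_two_cases	1	3	0
CHRNG	more_than_two_cases	3	3	0
DAAM2	more_than_two_cases	3	3	1
DNAH14	more_than_two_cases	4	4	0
DNAH2	more_than_two_cases	3	3	0
DNAH9	more_than_two_cases	3	3	0
FSIP2	more_than_two_cases	3	3	0
HLA-DRB1	more_than_two_cases	2	4	0
HRASLS	more_than_two_cases	1	3	0
IGFLR1	more_than_two_cases	2	2	1
KRT10	more_than_two_cases	1	5	0
LAMA1	more_than_two_cases	3	3	0
LRP5	more_than_two_cases	4	3	0
MRPS12	more_than_two_cases	1	3	0
NEB	more_than_two_cases	4	4	0
OBSCN	more_than_two_cases	5	5	0
TCOF1	more_than_two_cases	3	4	0
TNXB	more_than_two_cases	3	3	0
TTN	more_than_two_cases	8	8	0
UTRN	more_than_two_cases	3	3	0
VEGFB	more_than_two_cases	1	3	0
ZC3H3	more_than_two_cases	3	3	0
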