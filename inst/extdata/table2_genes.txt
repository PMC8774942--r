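# Published recurrence table transcription: genes with a rare variant in at
# least two AFF cases after damaging-variant prioritization (132 genes).
# '5-Sep' is kept verbatim from the published table (a spreadsheet-mangled
# form of SEPT5).
AASS
ABCA10
ABCA4
ABL2
ADAMTS12
ANAPC11
ANK3
ANKRD40
ARHGEF18
ARID1B
ASH1L
ATAD2
ATP10B
BIN1
C10orf54
C12orf42
C14orf159
C17orf107
C6
C9orf84
CA9
CDC42BPG
CERKL
CHAMP1
CLCN2
CRYBA1
CTSE
CUL7
CYYR1
DAB2IP
DAW1
DHX34
DNAH10
DNAH12
DNAH6
DYSF
EFHB
EP400
ERCC5
FAT4
FBLN7
FLJ00418
GBP3
GPX4
HK3
HPS6
IGFN1
IGSF10
IGSF22
KLHL33
LLGL1
MEX3D
MKS1
MMP20
MSLNL
NOD2
NUP153
OPLAH
PACSIN2
PARD6B
PCDHAC1
PDE4DIP
PISD
PLA2G4D
PSD3
PTH1R
PYHIN1
R3HDML
RET
RMDN1
RNF157
RNF34
RTEL1
SCN9A
5-Sep
SH3BP2
SHROOM4
SIRT5
SLC26A9
SLC2A7
SLC34A3
SLC52A2
SPTBN5
SRCAP
TAF15
TENM4
TJP3
TMEM143
TNRC6B
TOPORS
TSFM
TTC14
ZNF34
ZNF646
ZNF729
ZSCAN32
ACADL
C1orf87
CD1A
CITED4
GBA
IQSEC3
NSMAF
PPP2R1B
SERPINB2
SPTBN1
SYDE1
TNFRSF25
TRAPPC2L
TRIM32
C8orf46
CHRNG
DAAM2
DNAH14
DNAH2
DNAH9
FSIP2
HLA-DRB1
HRASLS
IGFLR1
KRT10
LAMA1
LRP5
MRPS12
NEB
OBSCN
TCOF1
TNXB
TTN
UTRN
VEGFB
ZC3H3
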