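# SYNTHETIC damaging-gene stand-in: the 132 recurrence-table genes plus
# LURAP1L, POLI and SYDE2 (singleton carriers of damaging variants).
5-Sep
AASS
ABCA10
ABCA4
ABL2
ACADL
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
C1orf87
C6
C8orf46
C9orf84
CA9
CD1A
CDC42BPG
CERKL
CHAMP1
CHRNG
CITED4
CLCN2
CRYBA1
CTSE
CUL7
CYYR1
DAAM2
DAB2IP
DAW1
DHX34
DNAH10
DNAH12
DNAH14
DNAH2
DNAH6
DNAH9
DYSF
EFHB
EP400
ERCC5
FAT4
FBLN7
FLJ00418
FSIP2
GBA
GBP3
GPX4
HK3
HLA-DRB1
HPS6
HRASLS
IGFLR1
IGFN1
IGSF10
IGSF22
IQSEC3
KLHL33
KRT10
LAMA1
LLGL1
LRP5
LURAP1L
MEX3D
MKS1
MMP20
MRPS12
MSLNL
NEB
NOD2
NSMAF
NUP153
OBSCN
OPLAH
PACSIN2
PARD6B
PCDHAC1
PDE4DIP
PISD
PLA2G4D
POLI
PPP2R1B
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
SERPINB2
SH3BP2
SHROOM4
SIRT5
SLC26A9
SLC2A7
SLC34A3
SLC52A2
SPTBN1
SPTBN5
SRCAP
SYDE1
SYDE2
TAF15
TCOF1
TENM4
TJP3
TMEM143
TNFRSF25
TNRC6B
TNXB
TOPORS
TRAPPC2L
TRIM32
TSFM
TTC14
TTN
UTRN
VEGFB
ZC3H3
ZNF34
ZNF646
ZNF729
ZSCAN32
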