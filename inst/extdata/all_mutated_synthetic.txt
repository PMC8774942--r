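# SYNTHETIC stand-in for the cohort's full mutated-gene list (455 genes:
# the real list derives from unavailable patient exomes). Contains the
# 132 recurrence-table genes, the 9 planted prior-study overlaps and
# synthetic filler symbols.
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
MUT001
MUT002
MUT003
MUT004
MUT005
MUT006
MUT007
MUT008
MUT009
MUT010
MUT011
MUT012
MUT013
MUT014
MUT015
MUT016
MUT017
MUT018
MUT019
MUT020
MUT021
MUT022
MUT023
MUT024
MUT025
MUT026
MUT027
MUT028
MUT029
MUT030
MUT031
MUT032
MUT033
MUT034
MUT035
MUT036
MUT037
MUT038
MUT039
MUT040
MUT041
MUT042
MUT043
MUT044
MUT045
MUT046
MUT047
MUT048
MUT049
MUT050
MUT051
MUT052
MUT053
MUT054
MUT055
MUT056
MUT057
MUT058
MUT059
MUT060
MUT061
MUT062
MUT063
MUT064
MUT065
MUT066
MUT067
MUT068
MUT069
MUT070
MUT071
MUT072
MUT073
MUT074
MUT075
MUT076
MUT077
MUT078
MUT079
MUT080
MUT081
MUT082
MUT083
MUT084
MUT085
MUT086
MUT087
MUT088
MUT089
MUT090
MUT091
MUT092
MUT093
MUT094
MUT095
MUT096
MUT097
MUT098
MUT099
MUT100
MUT101
MUT102
MUT103
MUT104
MUT105
MUT106
MUT107
MUT108
MUT109
MUT110
MUT111
MUT112
MUT113
MUT114
MUT115
MUT116
MUT117
MUT118
MUT119
MUT120
MUT121
MUT122
MUT123
MUT124
MUT125
MUT126
MUT127
MUT128
MUT129
MUT130
MUT131
MUT132
MUT133
MUT134
MUT135
MUT136
MUT137
MUT138
MUT139
MUT140
MUT141
MUT142
MUT143
MUT144
MUT145
MUT146
MUT147
MUT148
MUT149
MUT150
MUT151
MUT152
MUT153
MUT154
MUT155
MUT156
MUT157
MUT158
MUT159
MUT160
MUT161
MUT162
MUT163
MUT164
MUT165
MUT166
MUT167
MUT168
MUT169
MUT170
MUT171
MUT172
MUT173
MUT174
MUT175
MUT176
MUT177
MUT178
MUT179
MUT180
MUT181
MUT182
MUT183
MUT184
MUT185
MUT186
MUT187
MUT188
MUT189
MUT190
MUT191
MUT192
MUT193
MUT194
MUT195
MUT196
MUT197
MUT198
MUT199
MUT200
MUT201
MUT202
MUT203
MUT204
MUT205
MUT206
MUT207
MUT208
MUT209
MUT210
MUT211
MUT212
MUT213
MUT214
MUT215
MUT216
MUT217
MUT218
MUT219
MUT220
MUT221
MUT222
MUT223
MUT224
MUT225
MUT226
MUT227
MUT228
MUT229
MUT230
MUT231
MUT232
MUT233
MUT234
MUT235
MUT236
MUT237
MUT238
MUT239
MUT240
MUT241
MUT242
MUT243
MUT244
MUT245
MUT246
MUT247
MUT248
MUT249
MUT250
MUT251
MUT252
MUT253
MUT254
MUT255
MUT256
MUT257
MUT258
MUT259
MUT260
MUT261
MUT262
MUT263
MUT264
MUT265
MUT266
MUT267
MUT268
MUT269
MUT270
MUT271
MUT272
MUT273
MUT274
MUT275
MUT276
MUT277
MUT278
MUT279
MUT280
MUT281
MUT282
MUT283
MUT284
MUT285
MUT286
MUT287
MUT288
MUT289
MUT290
MUT291
MUT292
MUT293
MUT294
MUT295
MUT296
MUT297
MUT298
MUT299
MUT300
MUT301
MUT302
MUT303
MUT304
MUT305
MUT306
MUT307
MUT308
MUT309
MUT310
MUT311
MUT312
MUT313
MUT314
MUT315
NEB
NOD2
NSMAF
NUP153
OBSCN
OPLAH
OVLG1
OVLG2
OVLG3
OVLG4
OVLG5
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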