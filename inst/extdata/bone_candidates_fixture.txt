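# FIXTURE bone-metabolism/AFF literature candidate list.
# Reverse-assembled: the 12 published candidate genes plus 20 canonical
# bone-biology genes absent from the cohort's recurrence table, so that
# intersecting with the recurrence-table genes recovers exactly the 12.
# Not a faithful reconstruction of the literature lists it stands in for.
ALPL
COL1A1
COL1A2
CTSK
CUL7
DAAM2
DNAH10
DNAH12
ESR1
FDPS
GGPS1
IFITM5
LAMA1
LRP5
LRP6
MEX3D
OPTN
P3H1
PLS3
PTH1R
RUNX2
SFRP4
SLC34A3
SOST
SPTBN1
TNFRSF11B
TNFSF11
TNRC6B
TNXB
VDR
WNT1
WNT16
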