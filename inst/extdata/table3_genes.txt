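# Published candidate-gene table transcription: bone-metabolism/AFF genes
# with deleterious rare variants in >= 2 AFF cases (12 genes).
CUL7
DAAM2
DNAH10
DNAH12
LAMA1
LRP5
MEX3D
PTH1R
SLC34A3
SPTBN1
TNRC6B
TNXB
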