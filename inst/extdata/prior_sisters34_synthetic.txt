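# SYNTHETIC stand-in for the prior 3-sisters AFF study's 34-gene list
# (the real list is not printed in the source). Planted structure: 9 of
# these genes also appear in the all-mutated stand-in list, 4 of which
# (LURAP1L, MEX3D, POLI, SYDE2) are in the damaging set.
LURAP1L
MEX3D
OVLG1
OVLG2
OVLG3
OVLG4
OVLG5
POLI
SIS01
SIS02
SIS03
SIS04
SIS05
SIS06
SIS07
SIS08
SIS09
SIS10
SIS11
SIS12
SIS13
SIS14
SIS15
SIS16
SIS17
SIS18
SIS19
SIS20
SIS21
SIS22
SIS23
SIS24
SIS25
SYDE2
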