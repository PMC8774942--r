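# Worked-example variant enumerations for the DAAM2 and LRP5 genes:
# DAAM2 three carriers (one homozygous p.(P555L)) plus a fourth carrier
# whose p.(K776T) is SIFT-tolerated and falls at prioritization; LRP5
# four variants in three carriers (AFF07 carries two). Genomic
# coordinates, depths, qualities, frequencies and scores are synthetic
# (the source gives protein-level notation only) but fixed.
sample_id	chrom	pos	ref	alt	gene	hgvs_p	zygosity	dp	gq	consequence	maf_exac	maf_csvs	sift	polyphen	cadd
AFF01	6	39870000	C	T	DAAM2	p.(P555L)	homozygous	142	99	missense	2e-04		deleterious	probably_damaging	29.1
AFF02	6	39875000	C	A	DAAM2	p.(P582H)	heterozygous	120	95	missense			deleterious	probably_damaging	27.4
AFF03	6	39880000	G	T	DAAM2	p.(R989L)	heterozygous	138	99	missense	1e-04		deleterious	possibly_damaging	25.8
AFF04	6	39885000	A	C	DAAM2	p.(K776T)	heterozygous	150	99	missense	4e-04		tolerated	probably_damaging	23.5
AFF05	11	68080000	C	T	LRP5	p.(R258C)	heterozygous	133	92	missense	3e-04		deleterious	probably_damaging	31
AFF06	11	68115000	C	T	LRP5	p.(P1504L)	heterozygous	141	99	missense		0.001	deleterious	probably_damaging	26.2
AFF07	11	68100000	G	A	LRP5	p.(R1036Q)	heterozygous	129	96	missense	0.0012		deleterious	possibly_damaging	24.7
AFF07	11	68112000	C	T	LRP5	p.(S1482L)	heterozygous	147	99	missense	8e-04		deleterious	probably_damaging	28.3
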