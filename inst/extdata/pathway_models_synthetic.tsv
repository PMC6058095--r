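gene_symbol	pathway	model_accession
NtcA	ntca_induced	SYNM0001
glnA	ntca_induced	SYNM0002
pII	ntca_induced	SYNM0003
urtB	ntca_induced	SYNM0004
urtC	ntca_induced	SYNM0005
urtD	ntca_induced	SYNM0006
urtE	ntca_induced	SYNM0007
recD	ntca_induced	SYNM0008
amt1	ntca_induced	SYNM0009
argC	arg_biosynthesis	SYNM0010
argJ	arg_biosynthesis	SYNM0011
argH	arg_biosynthesis	SYNM0012
argE	arg_biosynthesis	SYNM0013
argG	arg_biosynthesis	SYNM0014
argF	arg_biosynthesis	SYNM0015
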