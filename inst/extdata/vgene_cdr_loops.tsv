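v_gene	chain	cdr1	cdr2	cdr25
TRAV-SYN1	A	DSAI	IQSS	FKG
TRAV-SYN2	A	TSGF	NVLD	LKG
TRAV-SYN3	A	DRGS	IYSN	MKG
TRBV-SYN1	B	SNHL	FRNQ	SVP
TRBV-SYN2	B	MNHE	SMNV	TAP
TRBV-SYN3	B	SGHR	YFSE	AIP
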