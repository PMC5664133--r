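chrX	153400000	153470000	OPN1LW_MW_region_approx
chr12	1901500	1906000	CACNA2D4_3UTR_approx
chr19	48336000	48338000	CRX_3UTR_approx
chr1	19541000	19543000	EMC1_3UTR_approx
chr5	149237000	149240000	PDE6A_3UTR_approx
chr8	10464000	10467000	RP1L1_3UTR_approx
chr11	8040000	8043000	TUB_3UTR_approx
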