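barcode_id	sequence	lnp_name
BC001	TAATATAT	LNP-CAD1
BC002	GTCAACGC	LNP-CAD2
BC003	TAGGATCC	LNP-CAD3
BC004	GGCGGATA	LNP-CAD4
BC005	CCGGCCAT	LNP-CAD5
BC006	ACCATATT	LNP-CAD6
BC007	ATGCCGAA	LNP-CAD7
BC008	GCGCTAAC	LNP-CAD8
BC_naked	ATGTCAAT	naked_control
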