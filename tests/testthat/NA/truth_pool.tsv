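mouse	organ	replicate	barcode_id	molecules
0	pool	1	BC001	36
0	pool	1	BC002	32
0	pool	1	BC003	26
0	pool	1	BC004	34
0	pool	1	BC005	46
0	pool	1	BC006	40
0	pool	1	BC007	39
0	pool	1	BC008	33
0	pool	1	BC_naked	31
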