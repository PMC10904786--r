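mouse	organ	barcode_id	molecules
1	heart	BC001	42
1	heart	BC002	31
1	heart	BC003	31
1	heart	BC004	42
1	heart	BC005	37
1	heart	BC006	24
1	heart	BC007	49
1	heart	BC008	43
1	heart	BC_naked	56
1	liver	BC001	39
1	liver	BC002	33
1	liver	BC003	31
1	liver	BC004	42
1	liver	BC005	25
1	liver	BC006	16
1	liver	BC007	23
1	liver	BC008	41
1	liver	BC_naked	26
1	spleen	BC001	46
1	spleen	BC002	57
1	spleen	BC003	44
1	spleen	BC004	42
1	spleen	BC005	34
1	spleen	BC006	32
1	spleen	BC007	33
1	spleen	BC008	14
1	spleen	BC_naked	21
1	lung	BC001	65
1	lung	BC002	24
1	lung	BC003	26
1	lung	BC004	46
1	lung	BC005	30
1	lung	BC006	24
1	lung	BC007	23
1	lung	BC008	20
1	lung	BC_naked	34
1	kidney	BC001	31
1	kidney	BC002	52
1	kidney	BC003	20
1	kidney	BC004	38
1	kidney	BC005	50
1	kidney	BC006	26
1	kidney	BC007	57
1	kidney	BC008	38
1	kidney	BC_naked	24
2	heart	BC001	43
2	heart	BC002	21
2	heart	BC003	24
2	heart	BC004	16
2	heart	BC005	28
2	heart	BC006	45
2	heart	BC007	48
2	heart	BC008	21
2	heart	BC_naked	15
2	liver	BC001	43
2	liver	BC002	31
2	liver	BC003	38
2	liver	BC004	42
2	liver	BC005	36
2	liver	BC006	43
2	liver	BC007	38
2	liver	BC008	61
2	liver	BC_naked	40
2	spleen	BC001	39
2	spleen	BC002	40
2	spleen	BC003	41
2	spleen	BC004	27
2	spleen	BC005	26
2	spleen	BC006	26
2	spleen	BC007	34
2	spleen	BC008	37
2	spleen	BC_naked	48
2	lung	BC001	20
2	lung	BC002	28
2	lung	BC003	45
2	lung	BC004	29
2	lung	BC005	49
2	lung	BC006	31
2	lung	BC007	32
2	lung	BC008	22
2	lung	BC_naked	37
2	kidney	BC001	40
2	kidney	BC002	25
2	kidney	BC003	84
2	kidney	BC004	42
2	kidney	BC005	26
2	kidney	BC006	40
2	kidney	BC007	43
2	kidney	BC008	33
2	kidney	BC_naked	51
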