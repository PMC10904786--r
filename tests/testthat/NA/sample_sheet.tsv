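sample_id	mouse	organ	role	fastq
m1_heart	1	heart	tissue	m1_heart.fastq
m1_liver	1	liver	tissue	m1_liver.fastq
m1_spleen	1	spleen	tissue	m1_spleen.fastq
m1_lung	1	lung	tissue	m1_lung.fastq
m1_kidney	1	kidney	tissue	m1_kidney.fastq
m2_heart	2	heart	tissue	m2_heart.fastq
m2_liver	2	liver	tissue	m2_liver.fastq
m2_spleen	2	spleen	tissue	m2_spleen.fastq
m2_lung	2	lung	tissue	m2_lung.fastq
m2_kidney	2	kidney	tissue	m2_kidney.fastq
pool_1	0	pool	pool	pool_1.fastq
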