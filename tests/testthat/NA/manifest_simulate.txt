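stage = simulate
package_version = 0.1.0
config_hash = 1f7b73f9
anchor_max_mm = 2
barcode_len = 8
comparison = one_vs_rest
dedup_method = directional
fastq_dir = NA
fc_threshold = 1
force = FALSE
gzip_fastq = FALSE
hit_denominator = library
max_mm = 1
min_dist = 3
molecules_per_organ = 300
mouse_sd = 0.3
n_barcodes = 8
n_mice = 2
n_pool_replicates = 1
naked_control = TRUE
off_targets = liver ,spleen
organ_of_interest = lung
out_dir = /tmp/RtmpTvitIs/filea708168fc4/out
pcr_cycles = 1
pcr_efficiency = 0.5
planted_affinity = 8
planted_barcodes = 
planted_organ = lung
prefix_seq = TCGGATCCTACGGTAACGCT
pseudocount = 0.5
q_threshold = 0.05
reads_per_sample = 600
rlu_aggregate = mean
rlu_table = NA
rlu_threshold = 100
sample_sheet = NA
seed = 5
seq_error_rate = 0.001
suffix_seq = AGATCGGAAGAGCACACGTC
umi_len = 8
verbose = 0
whitelist = NA
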