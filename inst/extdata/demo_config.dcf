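seed: 7
outdir: afptools_demo
stages: simulate count_repeats scan classify synteny southern
array.vector_len: 2000
array.flank_left_len: 1500
array.flank_right_len: 1500
array.unit_len: 3200
array.n_units: 4
array.per_unit_snv_rate: 0.0005
reads.n_reads: 250
reads.mean_len: 2500
reads.sd_len: 1000
reads.min_len: 300
repeat.bootstrap: 200
scan.scaffold_identity: 0.85
scan.cds_model: replaced
southern.enzyme: DraI
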