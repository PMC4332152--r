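{
  "seed": 11,
  "n_chromosomes": 1,
  "n_genes": 40,
  "strains": ["WT", "set1d"],
  "replicates": 2,
  "ip_marks": ["H3K4me3"],
  "n_fragments": 8000,
  "pcr_duplication_rate": 0.05,
  "emit_fastq": true,
  "diff_mark": "H3K4me3",
  "condition_a": "WT",
  "condition_b": "set1d",
  "cage_tags_per_gene": 60
}
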