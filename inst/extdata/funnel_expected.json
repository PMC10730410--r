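{
  "significant_eqtl_rows": 339,
  "candidate_variants": 66,
  "in_accessibility": 47,
  "in_accessibility_and_loops": 42,
  "post_qc": 42,
  "index_eqtls": 42,
  "significant_indices": 1,
  "replicated_loci": 1,
  "selected_genes": 0
}
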