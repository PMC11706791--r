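{
  "title": "copearch run report",
  "required": ["params", "stages"],
  "stage_names": ["cpg", "enrichment", "clustering", "depth", "ks"],
  "stage_required": {
    "cpg": ["summary", "tail_size"],
    "enrichment": ["n_terms_tested", "n_significant"],
    "clustering": ["subset", "ks", "per_chromosome"],
    "depth": ["n_genes", "n_outlier_high"],
    "ks": ["n_pairs", "mean_ks", "window_fractions"]
  }
}
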