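{
  "title": "ctcpanel pipeline summary",
  "description": "Required blocks and fields of the summary.json written by run_pipeline()",
  "required": {
    "config": ["pos_fc", "high_fc", "k_pos", "k_high", "reference_gene", "endpoint", "seed"],
    "panel": ["genes", "n_candidates"],
    "quantification": ["n_genes", "n_samples", "calibrator"],
    "classification": ["sample_level", "patient_level"],
    "association": ["n_tests", "min_p"],
    "survival": ["ctc_high", "hybrid_emt"]
  }
}
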