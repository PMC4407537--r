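# Default build configuration (all keys optional; shown with their defaults).
retention_enrichment_threshold: 2
resolution: 200
id_prefix: REGB
ctcf_target: CTCF
open_chromatin_target: open-chromatin
active_labels: [promoter_tss, promoter_flank, enhancer, ctcf]
decision_tree:
  default: low_activity
  rules:
    - when: "ctcf_correlation >= 0.25"
      label: ctcf
    - when: "tss_enrichment >= 5"
      label: promoter_tss
    - when: "tf_enrichment >= 2 & tss_enrichment >= 2"
      label: promoter_flank
    - when: "tf_enrichment >= 2"
      label: enhancer
    - when: "exon_enrichment >= 2"
      label: transcribed
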