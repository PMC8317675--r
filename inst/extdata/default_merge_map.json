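{
  "merge_map": {
    "upper lobe, lung": "lung",
    "lower lobe, lung": "lung",
    "middle lobe, lung": "lung",
    "lung not otherwise specified": "lung",
    "esophageal SCC, not otherwise specified": "esophageal SCC",
    "esophageal SCC, keratinizing, not otherwise specified": "esophageal SCC"
  },
  "exclude_tissues": [
    "thyroid gland",
    "brain"
  ],
  "_comment": "Default label merges and tissue exclusions for GDC-style metadata: sub-site lung labels collapse onto a single lung tissue, esophageal squamous cell carcinoma subtypes collapse onto one diagnosis, and heterogeneous (thyroid) or normal-free (brain) tissues are excluded. Users extend this file for their own cohorts; merges are data, not code."
}
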