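{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "shadetol pipeline summary",
  "type": "object",
  "required": ["seed", "control", "thresholds", "n_genotypes", "locations",
               "treatments", "stratum_means", "shade_effects",
               "category_counts", "tolerance_stability"],
  "properties": {
    "seed": {"type": "integer"},
    "control": {"type": "string"},
    "thresholds": {"type": "object"},
    "n_genotypes": {"type": "integer"},
    "locations": {"type": "array"},
    "treatments": {"type": "array"},
    "stratum_means": {"type": "array"},
    "shade_effects": {"type": "array"},
    "category_counts": {"type": "array"},
    "n_skipped_profiles": {"type": "integer"},
    "tolerance_stability": {"type": "object"},
    "split_plot": {"type": "array"},
    "two_way": {"type": "array"},
    "paired_correlations": {"type": "array"},
    "path": {"type": "array"},
    "pca": {"type": "array"},
    "transitions": {"type": "array"},
    "clusters": {"type": "object"},
    "importance": {"type": "object"}
  }
}
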