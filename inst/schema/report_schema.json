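{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "herdlca run report",
  "type": "object",
  "required": ["manifest", "systems", "ei_mean", "spread", "anova_ei",
               "pairwise_ei", "correlations", "sex_contrasts"],
  "properties": {
    "manifest": {
      "type": "object",
      "required": ["package", "version", "seed", "gwp", "allocation",
                   "config_hash"]
    },
    "systems": {"type": "array", "items": {"type": "string"}},
    "ei_mean": {"type": "object"},
    "representative": {"type": ["array", "null"]},
    "spread": {"type": "array"},
    "anova_ei": {"type": "array"},
    "pairwise_ei": {"type": "array"},
    "correlations": {"type": "array"},
    "sex_contrasts": {"type": "array"},
    "mc_intervals": {"type": ["array", "null"]}
  }
}
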