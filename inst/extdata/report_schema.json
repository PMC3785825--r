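{
  "required": ["parameters", "seed"],
  "types": {
    "parameters": "object",
    "seed": "number",
    "ensemble_size": "number",
    "n_contact_pairs": "number",
    "n_frequent_pairs": "number",
    "key_residues": "object",
    "selected_conformations": "array",
    "satisfied_fraction": "object",
    "covariation_hits": "array"
  }
}
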