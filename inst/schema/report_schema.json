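{
  "title": "bprsnet run report",
  "type": "object",
  "required": [
    "package_version",
    "config",
    "n_subjects",
    "n_items",
    "possible_edges",
    "n_edges",
    "edge_fraction_pct",
    "top_edges",
    "centrality",
    "communities"
  ],
  "properties": {
    "package_version": {"type": "string"},
    "config": {"type": "object"},
    "n_subjects": {"type": "integer"},
    "n_items": {"type": "integer"},
    "possible_edges": {"type": "integer"},
    "n_edges": {"type": "integer"},
    "edge_fraction_pct": {"type": "number"},
    "selected_lambda": {"type": "number"},
    "top_edges": {"type": "array"},
    "centrality": {"type": "array"},
    "communities": {"type": "object"},
    "permutation": {"type": "object"},
    "stability": {"type": "object"},
    "bootstrap": {"type": "object"},
    "timings": {"type": "object"}
  }
}
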