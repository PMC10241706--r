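{
  "name": "oncotype_dx",
  "kind": "grouped_linear_score",
  "provenance": "21-gene recurrence-score structure (16 cancer genes, grouped, with per-group floors and the classic low/intermediate/high cutpoints). Expression is min-max rescaled to the 0-15 reference scale; absolute scores are research-grade, not the commercial assay.",
  "genes": ["GRB7", "ERBB2", "ESR1", "PGR", "BCL2", "SCUBE2", "MKI67", "AURKA", "BIRC5", "CCNB1", "MYBL2", "MMP11", "CTSL2", "CD68", "GSTM1", "BAG1"],
  "groups": {
    "GRB7": "her2_group",
    "ERBB2": "her2_group",
    "ESR1": "er_group",
    "PGR": "er_group",
    "BCL2": "er_group",
    "SCUBE2": "er_group",
    "MKI67": "prolif_group",
    "AURKA": "prolif_group",
    "BIRC5": "prolif_group",
    "CCNB1": "prolif_group",
    "MYBL2": "prolif_group",
    "MMP11": "invasion_group",
    "CTSL2": "invasion_group",
    "CD68": "cd68",
    "GSTM1": "gstm1",
    "BAG1": "bag1"
  },
  "coefficients": {
    "her2_group": 0.47,
    "er_group": -0.34,
    "prolif_group": 1.04,
    "invasion_group": 0.1,
    "cd68": 0.05,
    "gstm1": -0.08,
    "bag1": -0.07
  },
  "clipping": {
    "her2_group": 8,
    "prolif_group": 6.5
  },
  "rescale_range": [0, 15],
  "intercept": 0,
  "scale_mult": 20,
  "scale_add": -134,
  "range": [0, 100],
  "risk_cutpoints": [18, 31],
  "risk_labels": ["low", "intermediate", "high"]
}
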