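{
  "name": "ror_pam50",
  "kind": "centroid_correlation_combination",
  "provenance": "Subtype-correlation risk-of-recurrence combination; coefficients follow the published subtype weighting, linearly rescaled to a 0-100 research scale (not the commercial ROR).",
  "genes": ["ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1", "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2", "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C", "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67", "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6", "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B", "TYMS", "UBE2C", "UBE2T"],
  "coefficients": {
    "LumA": -0.34,
    "LumB": 0.23,
    "HER2": 0.12,
    "Basal": 0.05
  },
  "scale_mult": 135.14,
  "scale_add": 45.95
}
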