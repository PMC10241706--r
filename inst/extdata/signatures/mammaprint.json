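{
  "name": "mammaprint",
  "kind": "template_correlation_threshold",
  "provenance": "SYNTHETIC 70-gene good-prognosis template in the style of a template-correlation signature; high risk when the Pearson correlation with the template falls below the threshold. Not the published template series.",
  "genes": ["ESR1", "PGR", "FOXA1", "MLPH", "NAT1", "SLC39A6", "MAPT", "BCL2", "BLVRA", "CXXC5", "GPR160", "BAG1", "MDM2", "TMEM45B", "SCUBE2", "GSTM1", "BIRC5", "CCNB1", "CDC20", "NUF2", "CEP55", "NDC80", "MKI67", "PTTG1", "RRM2", "TYMS", "UBE2C", "UBE2T", "ANLN", "CCNE1", "CDC6", "CENPF", "EXO1", "KIF2C", "MELK", "MYBL2", "ORC6", "ERBB2", "GRB7", "FGFR4", "MMP11", "CD68", "KRT5", "KRT14", "KRT17", "SFRP1", "FOXC1", "MIA", "CDH3", "EGFR", "PHGDH", "ACTR3B", "MYC", "ESM1", "IGFBP5", "FGF18", "TGFB3", "WISP1", "FLT1", "STK32B", "RASSF7", "DCK", "EXT1", "GNAZ", "MTDH", "PITRM1", "QSOX2", "PRC1", "DTL", "CDCA7"],
  "template": {
    "ESR1": 0.845,
    "PGR": 0.902,
    "FOXA1": 0.84,
    "MLPH": 0.91,
    "NAT1": 0.965,
    "SLC39A6": 0.848,
    "MAPT": 0.863,
    "BCL2": 0.902,
    "BLVRA": 0.849,
    "CXXC5": 0.881,
    "GPR160": 0.944,
    "BAG1": 0.948,
    "MDM2": 0.919,
    "TMEM45B": 0.807,
    "SCUBE2": 0.897,
    "GSTM1": 0.953,
    "BIRC5": -0.759,
    "CCNB1": -0.81,
    "CDC20": -0.935,
    "NUF2": -0.797,
    "CEP55": -0.771,
    "NDC80": -0.798,
    "MKI67": -0.792,
    "PTTG1": -0.778,
    "RRM2": -0.82,
    "TYMS": -0.735,
    "UBE2C": -0.776,
    "UBE2T": -0.862,
    "ANLN": -0.731,
    "CCNE1": -0.74,
    "CDC6": -0.759,
    "CENPF": -0.883,
    "EXO1": -0.828,
    "KIF2C": -0.768,
    "MELK": -0.798,
    "MYBL2": -0.783,
    "ORC6": -0.677,
    "ERBB2": -0.541,
    "GRB7": -0.606,
    "FGFR4": -0.486,
    "MMP11": -0.534,
    "CD68": -0.478,
    "KRT5": -0.641,
    "KRT14": -0.489,
    "KRT17": -0.606,
    "SFRP1": -0.624,
    "FOXC1": -0.608,
    "MIA": -0.557,
    "CDH3": -0.595,
    "EGFR": -0.681,
    "PHGDH": -0.6,
    "ACTR3B": -0.562,
    "MYC": -0.598,
    "ESM1": 0.059,
    "IGFBP5": 0.006,
    "FGF18": 0.055,
    "TGFB3": 0.106,
    "WISP1": -0.028,
    "FLT1": -0.004,
    "STK32B": -0.114,
    "RASSF7": -0,
    "DCK": -0.1,
    "EXT1": -0.095,
    "GNAZ": -0.154,
    "MTDH": 0.062,
    "PITRM1": 0.078,
    "QSOX2": 0.078,
    "PRC1": 0.257,
    "DTL": 0.239,
    "CDCA7": 0.003
  },
  "threshold": 0.4
}
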