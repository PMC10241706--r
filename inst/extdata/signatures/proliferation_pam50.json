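{
  "name": "proliferation_pam50",
  "kind": "mean_of_genes",
  "provenance": "The 11-gene PAM50 proliferation subset: mean normalized expression.",
  "genes": ["BIRC5", "CCNB1", "CDC20", "NUF2", "CEP55", "NDC80", "MKI67", "PTTG1", "RRM2", "TYMS", "UBE2C"]
}
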