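{
  "seed": 7,
  "sim": {
    "n_genes": 300,
    "n_marker_genes_per_type": 15,
    "n_events": 10000,
    "read_depth": 30000,
    "dna_contamination_fraction": 0.25,
    "intronic_read_fraction": 0.5,
    "fixation": "fixed",
    "rna_recovery_factor_unfixed": 0.1,
    "marker_exclusivity": 0.95,
    "read_length": 150,
    "ct_reference": 30,
    "qpcr_noise_sd": 0.15,
    "qpcr_replicates": 3
  },
  "mixture": {
    "endothelial": 0.02,
    "neuron": 0.3,
    "microglia": 0.05,
    "astrocyte": 0.2,
    "oligodendrocyte": 0.15,
    "OPC": 0.05,
    "other": 0.23
  },
  "gates": {
    "dapi_min": 316.227766016838,
    "ssc_max": 316.227766016838,
    "erg_hi_min": 2.5,
    "erg_lo_min": 1.5,
    "erg_lo_max": 2.5,
    "neun_min": 2
  },
  "sort": {
    "populations": ["ErgHi", "NeuN"],
    "n_target": 200
  },
  "quant": {
    "stranded": false,
    "min_count": 1
  },
  "enrichment": {
    "pseudocount": 0.5,
    "target": "endothelial",
    "other": "pooled",
    "min_log2": 1
  },
  "qc": {
    "erg_fraction_min": 0.005,
    "contamination_gene": "PTPRC",
    "contamination_tpm_max": 500
  },
  "qpcr": {
    "targets": ["CLDN5", "MAP2"],
    "housekeeping": "UBC"
  }
}
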