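# Synthetic tissue-expression table (TPM). The SNCA, APOA1 and UMOD values
# mirror published GTEx-style magnitudes; remaining rows are fillers.
gene	tissue	tpm
SNCA	substantia_nigra	20.81
SNCA	kidney_cortex	1.59
SNCA	liver	0.52
APOA1	kidney_cortex	0.77
APOA1	liver	220.0
APOA1	substantia_nigra	0.12
UMOD	kidney_cortex	1200.0
UMOD	substantia_nigra	0.01
UMOD	liver	0.02
TNF	kidney_cortex	2.10
TNF	substantia_nigra	1.40
TNF	liver	1.80
FN1	kidney_cortex	85.0
FN1	substantia_nigra	12.0
FN1	liver	140.0
IL6	kidney_cortex	0.90
IL6	substantia_nigra	0.40
IL6	liver	1.10
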