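EXOSOME	synthetic exosome-cargo catalog (ExoCarta-like stand-in)	APOA1	SNCA	FN1	TNF	SOD1	ALB	CD9	CD63	FLOT1	HSPA8
EV_PLASMA	synthetic plasma extracellular-vesicle catalog	APOA1	SNCA	ALB	FN1	CD9
EV_URINE	synthetic urine extracellular-vesicle catalog	APOA1	UMOD	CD63	ALB
EV_PLATELET	synthetic platelet-derived vesicle catalog	SNCA	FLOT1	CD9
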