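# Default assignment of named bridge genes to three non-mutually exclusive
# functional themes: inflammatory signaling / ECM dysregulation, metabolic /
# renin-angiotensin-system integration, lipid / protein homeostasis.
gene_symbol	theme
FN1	inflammatory_ecm
UMOD	inflammatory_ecm
TNF	inflammatory_ecm
IL6	inflammatory_ecm
IL1B	inflammatory_ecm
ACE	metabolic_ras
INS	metabolic_ras
TNF	metabolic_ras
IL6	metabolic_ras
APOA1	lipid_protein
SNCA	lipid_protein
INS	lipid_protein
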