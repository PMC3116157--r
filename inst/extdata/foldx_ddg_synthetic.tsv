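# SYNTHETIC predictor output table (structure-based ddG predictions, kcal/mol).
# HCAII_P237H (1.03) and HCAII_P237I (1.22) are published predictor values;
# the remaining rows are representative ~1 kcal/mol placeholders consistent
# with the published ranking (P237I/P237N least stable, P237F most stable
# among the predicted mutants) and are NOT published numbers.
variant	ddG_kcal_mol
HCAII_P237A	0.80
HCAII_P237T	0.95
HCAII_P237N	1.15
HCAII_P237I	1.22
HCAII_P237F	0.45
HCAII_P237H	1.03
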