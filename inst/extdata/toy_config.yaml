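model: toy_model.xml
expression: toy_expression.tsv
metabolomics: toy_metabolomics.tsv
medium: toy_medium.tsv
spent: toy_spent_medium.tsv
nameMap: toy_name_map.tsv
fluxIds:
  glucose: EX_glc
  glutamine: EX_gln
  lactate: EX_lac
  glutamate: EX_glu
biomassId: BIOMASS
nTotal: 5000
seed: 1
outDir: out
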