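# Example end-to-end pipeline configuration for `endosym run` /
# run_pipeline(): simulate a two-member consortium, detect split genes,
# tabulate stop-codon usage, score pathway presence and compare the
# genomes.
seed: 42
simulate:
  genomes:
    symA:
      genome_length: 60000
      gc_target: 0.20
      n_genes: 60
      n_split_genes: 8
      pathway_assignment:
        biotin: [bioC, bioF, bioA, bioD, bioB]
        cysteine: [cysE, cysK]
    symB:
      genome_length: 60000
      gc_target: 0.25
      n_genes: 60
      pathway_assignment:
        leucine: [leuA, leuB, leuC, leuD]
        valine: [ilvB, ilvC, ilvD, ilvE]
splits:
  max_gap: 30
  min_half_length: 10
pathways:
  whitelist: [ilvA, hisN, yigB]
  consortia:
    pair: [symA, symB]
# pairwise comparison is meaningful for closely related genomes; the
# self-comparison here demonstrates the report format
compare:
  pairs:
    - [symA, symA]
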