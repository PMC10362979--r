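schema: mdace-annotation/1
fragment:
  coordinate_offset: 1040
  frame_offset: 0
exons:
- start: 1
  end: 534
- start: 621
  end: 825
sites:
- label: V260L
  residue: 260
  codon_local_start: 133
  variable_offset: 0
  variable_position_label: 1174
  wildtype_codon: GTG
  wildtype_aa: V
  resistant:
    T: L
    C: L
- label: A316S
  residue: 316
  codon_local_start: 301
  variable_offset: 0
  variable_position_label: 1341
  wildtype_codon: GCC
  wildtype_aa: A
  resistant:
    T: S
- label: G342A/V
  residue: 342
  codon_local_start: 433
  variable_offset: 1
  variable_position_label: 1473
  wildtype_codon: GGA
  wildtype_aa: G
  resistant:
    T: V
    C: A
- label: F407Y
  residue: 407
  codon_local_start: 628
  variable_offset: 1
  variable_position_label: 1668
  wildtype_codon: TTT
  wildtype_aa: F
  resistant:
    A: 'Y'
catalog: allele_catalog.tsv
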