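# Priority decision table for biallelic candidate findings.
# First matching rule wins: hard flags -> Exclude; then Top, Middle, Low.
exclude_flags:
  - common_in_callset
  - no_segregation
  - in_cis
  - no_second_hit
pathogenic_classes: [P, LP]
top:
  # biallelic genotype: a homozygote, or a het pair phased in trans
  phases: [hom, in_trans]
  require_all_pathogenic: true
  require_mane_coding: true
middle:
  # some pathogenic support but unresolved phase or a VUS partner
  require_mane_coding: true
  min_pathogenic: 1
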