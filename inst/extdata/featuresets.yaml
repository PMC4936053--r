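# Gene-set definitions for the presence/absence census. Members are gene
# symbols matched against GENE_SYMBOL annotations; swap in Pfam/TIGRFAM
# accessions to match a different annotator. The complex I set lists the 11
# subunits expected in this lineage (the NADH dehydrogenase module NuoEFG is
# ancestrally absent); T9SS lists the ten core components with the PorXY
# regulators as a separate set.
- name: complex_I
  namespace: GENE_SYMBOL
  required: [nuoA, nuoB, nuoC, nuoD, nuoH, nuoI, nuoJ, nuoK, nuoL, nuoM, nuoN]
  complete_rule: all
- name: atp_synthase
  namespace: GENE_SYMBOL
  required: [atpA, atpB, atpC, atpD, atpE, atpF, atpG, atpH]
  complete_rule: all
- name: complex_II
  namespace: GENE_SYMBOL
  required: [frdA, frdB, frdC]
  complete_rule: all
- name: nqr
  namespace: GENE_SYMBOL
  required: [nqrA, nqrB, nqrC, nqrD, nqrE, nqrF]
  complete_rule: all
- name: cydAB
  namespace: GENE_SYMBOL
  required: [cydA, cydB]
  complete_rule: all
- name: t9ss
  namespace: GENE_SYMBOL
  required: [porK, porL, porM, porN, porP, porT, porU, porV, porW, sov]
  complete_rule: all
- name: t9ss_regulation
  namespace: GENE_SYMBOL
  required: [porX, porY]
  complete_rule: all
- name: urease
  namespace: GENE_SYMBOL
  required: [ureA, ureB, ureC]
  complete_rule: all
- name: oxalate_degradation
  namespace: GENE_SYMBOL
  required: [frc, oxc, oxlT]
  complete_rule: all
- name: superoxide_dismutase
  namespace: GENE_SYMBOL
  required: [sodA]
  complete_rule: all
- name: catalase
  namespace: GENE_SYMBOL
  required: [katE]
  complete_rule: all
- name: peroxiredoxin_ahpCF
  namespace: GENE_SYMBOL
  required: [ahpC, ahpF]
  complete_rule: all
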