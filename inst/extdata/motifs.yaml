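# Published uniparental haplotype motifs.
# Y-STR motifs: classical 6-locus modal haplotypes and their extended
# 12-locus versions; alleles in standard (forensic) nomenclature, DYS439
# already corrected. mtDNA motifs: HVS-I substitution sets relative to the
# rCRS. hg_context is the haplogroup the motif was described in; matching
# does not enforce it (haplogroup stratification happens in count tables).
version: 1
y_motifs:
  LMH:
    system: ystr6
    hg_context: R1a
    alleles: {DYS19: 16, DYS388: 12, DYS390: 25, DYS391: 10, DYS392: 11, DYS393: 13}
  eLMH:
    system: ystr12
    hg_context: R1a
    alleles: {DYS393: 13, DYS390: 25, DYS19: 16, DYS391: 10, DYS385a: 11,
              DYS385b: 14, DYS426: 12, DYS388: 12, DYS439: 10, DYS389I: 13,
              DYS392: 11, DYS389II: 30}
  CMH:
    system: ystr6
    hg_context: J1
    alleles: {DYS19: 14, DYS388: 16, DYS390: 23, DYS391: 10, DYS392: 11, DYS393: 12}
  eCMH:
    system: ystr12
    hg_context: J1
    alleles: {DYS393: 12, DYS390: 23, DYS19: 14, DYS391: 10, DYS385a: 13,
              DYS385b: 15, DYS426: 11, DYS388: 16, DYS439: 12, DYS389I: 13,
              DYS392: 11, DYS389II: 30}
  GAL:
    system: ystr6
    hg_context: J1
    alleles: {DYS19: 14, DYS388: 17, DYS390: 23, DYS391: 11, DYS392: 11, DYS393: 12}
  IP:
    system: ystr6
    hg_context: J1
    alleles: {DYS19: 14, DYS388: 17, DYS390: 22, DYS391: 11, DYS392: 11, DYS393: 12}
mt_motifs:
  K1:
    system: hvs1
    hg_context: K1a9
    substitutions: [16093C, 16224C, 16311C, 16519C, 16524G]
  K2:
    system: hvs1
    hg_context: K1a1b1a
    substitutions: [16224C, 16234T, 16311C, 16519C]
  K3:
    system: hvs1
    hg_context: K2a2a
    substitutions: [16224C, 16311C, 16519C]
  "N":
    system: hvs1
    hg_context: N1b1
    substitutions: [16145A, 16176A, 16223T, 16390A, 16519C]
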