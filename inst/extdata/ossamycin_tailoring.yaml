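# Post-PKS tailoring of the ossamycin macrolactone. The four cytochrome
# P450 hydroxylations (C-4, C-8, C-10 in the macrocycle; C-35 on the
# branched side chain, customary feeding-study numbering) are not firmly
# assigned to individual enzymes; candidate agents are listed. Glycosyl transfer of
# l-ossamine requires the prior C-8 hydroxylation. The spiroacetal closes
# the C-25 ketone onto the C-21/C-29 hydroxyls (ketal convention: -H2O);
# the side-chain hemiacetal (C-19 ketone + C-35 hydroxyl) is
# formula-neutral connectivity.
events:
  - {kind: hydroxylation, site: C-4, agent: "P450 (OssL/OssK/OssM/OssF, unassigned)"}
  - {kind: hydroxylation, site: C-8, agent: "P450 (OssL/OssK/OssM/OssF, unassigned)"}
  - {kind: hydroxylation, site: C-10, agent: "P450 (OssL/OssK/OssM/OssF, unassigned)"}
  - {kind: hydroxylation, site: C-35, agent: "P450 (OssL/OssK/OssM/OssF, unassigned)"}
  - {kind: spiroacetal, site: C-25, partners: [C-21, C-29], agent: "OssO (putative spirocyclase)", convention: ketal}
  - {kind: hemiacetal, site: C-19, partners: [C-35], agent: spontaneous}
  - {kind: glycosylation, site: C-8, agent: OssGT, sugar: from_pathway}
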