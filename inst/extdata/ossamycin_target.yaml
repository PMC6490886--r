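# Target polyketide backbone for ossamycin: 15 extension cycles on a
# propionate starter, macrolactonization at the C-23 hydroxyl (24-membered
# ring). Cycle chemistry is the realized product chemistry (so cycle 2 is
# malonyl although the AT2 motif predicts methylmalonyl). "reduction" is the
# state of the beta carbon processed in that cycle, i.e. backbone carbon
# 2*(15-cycle)+3: the KR-less cycles 4 and 7 leave the C-25 (spiroacetal)
# and C-19 (side-chain hemiacetal) ketones. Cells that are figure-resident
# in the source are marked confidence: low.
name: ossamycin backbone
starter:
  unit: propionate
  carbons: 3
cyclization_carbon: 23
extensions:
  - {cycle: 1, extender: methylmalonyl, reduction: hydroxyl, alpha_stereo: 2R, beta_stereo: 3R, confidence: low}
  - {cycle: 2, extender: malonyl, reduction: hydroxyl, beta_stereo: 3R, confidence: high}
  - {cycle: 3, extender: malonyl, reduction: methylene, confidence: low}
  - {cycle: 4, extender: methylmalonyl, reduction: ketone, confidence: high}
  - {cycle: 5, extender: malonyl, reduction: hydroxyl, beta_stereo: 3R, confidence: high}
  - {cycle: 6, extender: methylmalonyl, reduction: hydroxyl, alpha_stereo: 2R, beta_stereo: 3R, confidence: low}
  - {cycle: 7, extender: unusual-alkylmalonyl, reduction: ketone, confidence: high}
  - {cycle: 8, extender: malonyl, reduction: enoyl, confidence: low}
  - {cycle: 9, extender: malonyl, reduction: methylene, confidence: high}
  - {cycle: 10, extender: malonyl, reduction: methylene, confidence: high}
  - {cycle: 11, extender: methylmalonyl, reduction: methylene, alpha_stereo: 2S, confidence: high}
  - {cycle: 12, extender: malonyl, reduction: methylene, confidence: low}
  - {cycle: 13, extender: malonyl, reduction: methylene, confidence: low}
  - {cycle: 14, extender: malonyl, reduction: hydroxyl, beta_stereo: 3R, confidence: low}
  - {cycle: 15, extender: methylmalonyl, reduction: hydroxyl, alpha_stereo: 2R, beta_stereo: 3R, confidence: low}
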