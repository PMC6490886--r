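ossamycin_build <- function() {
  line <- build_modules(ossamycin_domain_calls())
  tgt <- ossamycin_target()
  ord <- order_multienzymes(line, tgt)
  modules <- do.call(rbind, lapply(as.character(ord), function(p)
    line$modules[line$modules$protein == p & !line$modules$malformed, ,
                 drop = FALSE]))
  list(line = line, target = tgt, modules = modules,
       iteration = attr(ord, "iteration"))
}

test_that("the assembled ossamycin chain has 33 backbone carbons", {
  b <- ossamycin_build()
  chain <- assemble_chain(b$line$loading, b$iteration, b$modules, b$target)
  expect_identical(chain$backbone_carbon_count, 33L)   # 3 + 2 x 15
  expect_identical(nrow(chain$units), 15L)
  # the unusual extender carries the branched C4 block beyond the backbone
  uu <- chain$units[chain$units$extender == "unusual-alkylmalonyl", ]
  expect_identical(uu$side_carbons, "34,35,36,37")
  expect_identical(uu$alpha_substituent, "isobutyl")
  # carbon bookkeeping: cycle 2 forms C-27/C-28
  expect_identical(chain$units$carbonyl_carbon[2], 27L)
  expect_identical(chain$units$alpha_carbon[2], 28L)
  # the spiroacetal and hemiacetal ketones sit at C-25 and C-19
  expect_identical(unname(chain$carbon_states[c("C25", "C19")]),
                   c("ketone", "ketone"))
})

test_that("acetate starter plus one unreduced malonyl cycle is acetoacetate", {
  loading <- list(starter_unit = "acetate", starter_carbons = 2L)
  calls <- make_calls("p1", list(d_ks(), d_at(), d_acp()))
  line <- build_modules(calls)
  tgt <- make_target("malonyl", "ketone", starter_carbons = 2L,
                     starter_unit = "acetate")
  it <- detect_iteration(line$modules, tgt)
  chain <- assemble_chain(loading, it, line$modules, tgt)
  expect_identical(chain$backbone_carbon_count, 4L)
  expect_identical(format(pksdecode:::.chain_formula(chain)), "C4H6O3")
})

test_that("ring size is site + 1 and requires a hydroxyl at the site", {
  b <- ossamycin_build()
  chain <- assemble_chain(b$line$loading, b$iteration, b$modules, b$target)
  mac <- macrolactonize(chain, 23)
  expect_identical(mac$ring_size, 24L)
  expect_false(mac$implausible)
  expect_error(macrolactonize(chain, 25), "ketone")
  expect_error(macrolactonize(chain, 13), "not hydroxyl")

  # tiny beta-lactone arithmetic: 4-carbon chain with 3-OH
  loading <- list(starter_unit = "acetate", starter_carbons = 2L)
  calls <- make_calls("p1", list(d_ks(), d_at(), d_kr(), d_acp()))
  line <- build_modules(calls)
  tgt <- make_target("malonyl", "hydroxyl", starter_carbons = 2L)
  it <- detect_iteration(line$modules, tgt)
  small <- assemble_chain(loading, it, line$modules, tgt)
  lac <- macrolactonize(small, 3)
  expect_identical(lac$ring_size, 4L)
  expect_true(lac$implausible)
})

test_that("suppressing the iteration gives the 22-membered homologue", {
  b <- ossamycin_build()
  tgt14 <- drop_cycle(b$target, 10)
  expect_identical(nrow(tgt14$extensions), 14L)
  expect_identical(tgt14$cyclization_carbon, 21L)
  it14 <- detect_iteration(b$modules, tgt14)
  expect_identical(length(it14$iterated_modules), 0L)
  chain14 <- assemble_chain(b$line$loading, it14, b$modules, tgt14)
  expect_identical(chain14$backbone_carbon_count, 31L)
  mac14 <- macrolactonize(chain14, tgt14$cyclization_carbon)
  expect_identical(mac14$ring_size, 22L)
})

test_that("tailoring events accumulate exact formula deltas", {
  b <- ossamycin_build()
  chain <- assemble_chain(b$line$loading, b$iteration, b$modules, b$target)
  mac <- macrolactonize(chain, 23)
  f0 <- mac$formula
  events <- ossamycin_tailoring()
  sugar <- residue_formula(ossamine_pathway())
  mac2 <- apply_tailoring(mac, events, sugar = sugar)
  # net delta: +4 O (hydroxylations) - H2O (spiroketal) + (sugar - H2O)
  expected <- formula_add(
    formula_add(f0, c(O = 4)),
    pksdecode:::formula_delta(sugar, parse_formula("H4O2")))
  expect_identical(unclass(mac2$formula), unclass(expected))
  expect_identical(length(mac2$tailoring), length(events))

  # empty event list leaves the macrolactone unchanged
  mac3 <- apply_tailoring(mac, list(), sugar = sugar)
  expect_identical(unclass(mac3$formula), unclass(f0))

  # glycosylation before the C-8 hydroxylation is rejected
  glyco_first <- events[c(7, 1, 2, 3, 4, 5, 6)]
  expect_error(apply_tailoring(mac, glyco_first, sugar = sugar),
               "requires a prior hydroxylation")
  expect_error(apply_tailoring(mac, list(list(kind = "oxidation",
                                              site = "C-4"))),
               "unknown tailoring event")
})

test_that("independent events commute; only the C-8 dependency orders them", {
  b <- ossamycin_build()
  chain <- assemble_chain(b$line$loading, b$iteration, b$modules, b$target)
  mac <- macrolactonize(chain, 23)
  events <- ossamycin_tailoring()
  sugar <- residue_formula(ossamine_pathway())
  ref <- apply_tailoring(mac, events, sugar = sugar)$formula
  perm <- events[c(4, 2, 1, 3, 6, 5, 7)]  # keeps OH@C-8 before glycosylation
  expect_identical(unclass(apply_tailoring(mac, perm, sugar = sugar)$formula),
                   unclass(ref))
})

test_that("masses match the per-element oracle and the hydroxyl delta", {
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)
  b <- ossamycin_build()
  chain <- assemble_chain(b$line$loading, b$iteration, b$modules, b$target)
  mac <- apply_tailoring(macrolactonize(chain, 23), ossamycin_tailoring())
  m_full <- compute_mass(mac)
  expect_equal(m_full$monoisotopic_mass, oracle_mass(mac$formula),
               tolerance = 1e-4)
  expect_equal(m_full$mh_plus - m_full$monoisotopic_mass, 1.00728,
               tolerance = 1e-4)
  # removing one hydroxylation changes the mass by exactly one oxygen
  events_minus <- ossamycin_tailoring()[-3]
  mac_minus <- apply_tailoring(macrolactonize(chain, 23), events_minus)
  m_minus <- compute_mass(mac_minus)
  expect_equal(m_full$monoisotopic_mass - m_minus$monoisotopic_mass,
               15.9949, tolerance = 1e-4)
})

test_that("exported line notation round-trips through the formula parser", {
  # minimal 4-carbon lactone
  loading <- list(starter_unit = "acetate", starter_carbons = 2L)
  calls <- make_calls("p1", list(d_ks(), d_at(), d_kr(), d_acp()))
  line <- build_modules(calls)
  tgt <- make_target("malonyl", "hydroxyl", starter_carbons = 2L)
  it <- detect_iteration(line$modules, tgt)
  small <- macrolactonize(assemble_chain(loading, it, line$modules, tgt), 3)
  smi <- export_structure(small)
  expect_identical(unclass(formula_from_smiles(smi)), unclass(small$formula))

  b <- ossamycin_build()
  chain <- assemble_chain(b$line$loading, b$iteration, b$modules, b$target)
  mac <- apply_tailoring(macrolactonize(chain, 23), ossamycin_tailoring())
  smi <- export_structure(mac)
  expect_identical(unclass(formula_from_smiles(smi)), unclass(mac$formula))
  # the full model: 33 backbone + 5 methyl + 4 side-chain + 8 sugar carbons
  expect_identical(unname(unclass(formula_from_smiles(smi))["C"]), 50L)
  # without stereo annotations the formula is unchanged
  smi_plain <- export_structure(mac, stereo = FALSE)
  expect_false(grepl("@", smi_plain, fixed = TRUE))
  expect_identical(unclass(formula_from_smiles(smi_plain)),
                   unclass(mac$formula))
})
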