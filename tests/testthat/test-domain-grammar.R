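test_that("planted domains are found in order; decoys yield nothing", {
  cfg <- generator_config(seed = 1L,
                          proteins = list(list(list(at = "malonyl", kr = "B1"))),
                          loading = NULL, te = FALSE, decoy_count = 1L)
  line <- emit_line(cfg)
  pks <- line$proteins[["synpks01"]]
  hits <- scan_domains(pks, protein_id = "synpks01")
  expect_identical(hits$domain_type, c("KS", "AT", "KR", "ACP"))
  expect_true(all(diff(hits$start) > 0))
  expect_true(all(hits$end >= hits$start))
  expect_false(any(hits$partial))
  # intervals agree with where the generator planted the blocks
  expect_identical(hits$start, unname(line$truth$start[
    line$truth$protein == "synpks01"]))

  decoy <- line$proteins[["decoy01"]]
  expect_identical(nrow(scan_domains(decoy)), 0L)
  shuffled <- paste(sample(strsplit(pks, "")[[1]]), collapse = "")
  expect_identical(nrow(scan_domains(shuffled)), 0L)

  expect_error(scan_domains("MAB1CDEF"), "illegal character")
})

test_that("a loading didomain is typed KSQ, not KS", {
  cfg <- generator_config(seed = 3L, proteins = list(list()),
                          loading = "methylmalonyl", te = FALSE)
  line <- emit_line(cfg)
  hits <- scan_domains(line$proteins[[1]])
  expect_identical(hits$domain_type, c("KSQ", "AT", "ACP"))
  expect_identical(hits$ksq[1], "Q")
})

test_that("AT fingerprint rules call the extender unit", {
  expect_identical(classify_at("GHSQ", "HAFH")$substrate, "malonyl")
  for (x in c("GHSI", "GHSL", "GHSV"))
    expect_identical(classify_at(x, "YASH")$substrate, "methylmalonyl")
  spgh <- classify_at("GHSV", "SPGH")
  expect_identical(spgh$substrate, "unusual-alkylmalonyl")
  expect_match(spgh$rule, "SPGH")
  expect_identical(classify_at("GHSV", "VASH")$substrate,
                   "unusual-alkylmalonyl")
  disc <- classify_at("GHSQ", "YASH")
  expect_identical(disc$substrate, "unknown")
  expect_true(disc$discordant)
  expect_identical(classify_at("AHSQ", "HAFH")$substrate, "unknown")
})

test_that("KR rules call activity, stereotype and configuration", {
  b1 <- classify_kr(list(kr_tyr = "Y", kr_lys = "K", kr_ser = "S",
                         kr_ldd = "LDD", kr_trp = "L", kr_qh = "Q"))
  expect_true(b1$active)
  expect_identical(b1$kr_type, "B1")
  expect_identical(b1$beta_dl, "d")
  expect_identical(b1$alpha_config, "2R")

  a1 <- classify_kr(list(kr_tyr = "Y", kr_lys = "K", kr_ser = "S",
                         kr_ldd = "AGA", kr_trp = "W", kr_qh = "Q"))
  expect_identical(a1$kr_type, "A1")
  expect_identical(a1$alpha_config, "2S")
  expect_identical(a1$beta_dl, "l")

  a2 <- classify_kr(list(kr_tyr = "Y", kr_lys = "K", kr_ser = "S",
                         kr_ldd = "AGA", kr_trp = "W", kr_qh = "H"))
  expect_identical(a2$kr_type, "A2")
  expect_identical(a2$alpha_config, "2R")   # as published
  expect_match(a2$note, "coincide")
  expect_identical(classify_kr(list(kr_tyr = "Y", kr_lys = "K", kr_ser = "S",
                                    kr_ldd = "AGA", kr_trp = "W",
                                    kr_qh = "H"), a2_alpha = "2S")$alpha_config,
                   "2S")

  dead <- classify_kr(list(kr_tyr = "F", kr_lys = "K", kr_ser = "S",
                           kr_ldd = "LDD", kr_trp = "L", kr_qh = "Q"))
  expect_false(dead$active)
  expect_identical(dead$kr_type, "unknown")
  expect_match(dead$note, "Phe")

  # Lys/Ser absence downgrades confidence, not the call
  weak <- classify_kr(list(kr_tyr = "Y", kr_lys = "R", kr_ser = "S",
                           kr_ldd = "LDD", kr_trp = "L", kr_qh = "Q"))
  expect_true(weak$active)
  expect_identical(weak$confidence, "reduced")
})

test_that("DH rules require both the His and Asp motifs", {
  expect_true(classify_dh("H", "D")$active)
  arg <- classify_dh("R", "D")
  expect_false(arg$active)
  expect_identical(arg$reason, "His→Arg")
  tyr <- classify_dh("Y", "D")
  expect_identical(tyr$reason, "His→Tyr")
  both <- classify_dh("R", "E")
  expect_match(both$reason, "His→Arg; Asp→Glu")
})

test_that("ER Tyr motif sets the alpha outcome", {
  expect_identical(classify_er("Y")$alpha_outcome, "2S")
  expect_identical(classify_er("V")$alpha_outcome, "2R")
  none <- classify_er(NULL)
  expect_false(none$present)
  expect_identical(none$alpha_outcome, "n/a")
})

test_that("classifiers enforce the domain-type contract", {
  hits <- make_calls("p1", list(d_ks(), d_at(), d_kr(), d_acp()))
  expect_error(classify_at(hits[hits$domain_type == "KR", ]),
               "contract violation")
  expect_error(classify_kr(hits[hits$domain_type == "AT", ]),
               "contract violation")
  expect_error(classify_dh(hits[hits$domain_type == "AT", ]),
               "contract violation")
  expect_error(classify_er(hits[hits$domain_type == "KS", ]),
               "contract violation")
})

test_that("calls depend only on fingerprints, never on flanking sequence", {
  cfg <- generator_config(seed = 11L,
                          proteins = list(list(
                            list(at = "methylmalonyl", kr = "A2",
                                 dh = "active", er = "tyr"))),
                          loading = NULL, te = FALSE, mutation_rate = 0)
  base <- emit_line(cfg)$proteins[[1]]
  base_calls <- classify_domains(scan_domains(base))
  key <- c("domain_type", "at_substrate", "kr_type", "dh_active", "er_alpha")

  set.seed(42)
  profiles <- pks_profiles()
  protected <- rep(FALSE, nchar(base))
  hits <- scan_domains(base)
  for (i in seq_len(nrow(hits))) {
    pf <- profiles[[if (hits$domain_type[i] == "KSQ") "KS"
                    else hits$domain_type[i]]]
    origin <- hits$start[i]
    a0 <- origin + pf$anchor_start - 1L
    protected[seq(a0, a0 + nchar(pf$anchor_regex) - 1L)] <- TRUE
    for (sl in pf$slots) {
      idx <- origin + sl$offset - 1L
      protected[seq(idx, idx + sl$length - 1L)] <- TRUE
    }
  }
  for (rep_i in 1:20) {
    chars <- strsplit(base, "")[[1]]
    mut <- sample(which(!protected), 30L)
    chars[mut] <- sample(c("A", "G", "E", "R", "T"), 30L, replace = TRUE)
    mutated <- paste(chars, collapse = "")
    mcalls <- classify_domains(scan_domains(mutated))
    if (nrow(mcalls) != nrow(base_calls)) {
      # a mutation created a spurious anchor elsewhere; regenerate
      next
    }
    expect_identical(mcalls[, key], base_calls[, key])
  }
})
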