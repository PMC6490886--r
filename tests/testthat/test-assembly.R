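test_that("the ossamycin call fixture yields 14 modules, loading and TE", {
  line <- build_modules(ossamycin_domain_calls())
  expect_identical(nrow(line$modules), 14L)
  expect_false(any(line$modules$malformed))
  expect_identical(line$loading$starter_unit, "propionate")
  expect_identical(line$loading$protein, "OssA1")
  expect_identical(line$te_protein, "OssA8")
  expect_identical(unname(line$per_protein),
                   c(2L, 2L, 3L, 1L, 1L, 1L, 2L, 2L))
  # KR-less modules 4 and 7 stay at ketone; inactive DH caps at hydroxyl
  expect_identical(line$modules$reduction_level[c(4, 7)],
                   c("ketone", "ketone"))
  expect_identical(line$modules$reduction_level[1], "hydroxyl")
  expect_identical(line$modules$dh_reason[1], "His→Arg")
  expect_identical(line$modules$dh_reason[7], "His→Tyr")
  expect_identical(line$modules$at_substrate[7], "unusual-alkylmalonyl")
})

test_that("restricting the fixture to OssA7+OssA8 gives four modules", {
  calls <- ossamycin_domain_calls()
  sub <- calls[calls$protein %in% c("OssA7", "OssA8"), ]
  line <- build_modules(sub)
  expect_identical(nrow(line$modules), 4L)
})

test_that("a minimal KS-AT-ACP protein makes one ketone-level module", {
  calls <- make_calls("p1", list(d_ks(), d_at(), d_acp()))
  line <- build_modules(calls)
  expect_identical(nrow(line$modules), 1L)
  expect_identical(line$modules$reduction_level, "ketone")
  expect_false(line$modules$malformed)
})

test_that("orphan domains are reported and flagged malformed", {
  calls <- make_calls("p1", list(d_acp(), d_ks(), d_at(), d_acp()))
  expect_warning(line <- build_modules(calls), "orphan ACP")
  expect_identical(nrow(line$modules), 1L)
  calls2 <- make_calls("p1", list(d_ks(), d_at(), d_kr()))  # never closed
  expect_warning(line2 <- build_modules(calls2), "malformed")
  expect_true(line2$modules$malformed)
})

test_that("fixture ordering recovers the annotated multienzyme order", {
  line <- build_modules(ossamycin_domain_calls())
  ord <- order_multienzymes(line, ossamycin_target())
  expect_identical(as.character(ord), paste0("OssA", 1:8))
  # the only mismatch is the shifted AT2 preference
  expect_identical(attr(ord, "score"), 1)
})

test_that("fixture iteration maps one module onto cycles 9 and 10", {
  line <- build_modules(ossamycin_domain_calls())
  tgt <- ossamycin_target()
  ord <- order_multienzymes(line, tgt)
  it <- attr(ord, "iteration")
  expect_identical(length(it$iterated_modules), 1L)
  expect_identical(it$stutters$cycles, "9,10")
  expect_identical(unique(it$cycle_to_module[9:10]), it$iterated_modules)
  # both stuttered cycles are malonyl and fully reduced
  expect_identical(tgt$extensions$extender[9:10], rep("malonyl", 2))
  expect_identical(tgt$extensions$reduction[9:10], rep("methylene", 2))
  # the AT2 discordance is in the discrepancy list
  d <- it$discrepancies
  expect_true(any(d$cycle == 2 & d$field == "extender" &
                    d$module_value == "methylmalonyl" &
                    d$target_value == "malonyl"))
})

test_that("equal cycle and module counts give the identity mapping", {
  calls <- make_calls("p1", list(
    d_ks(), d_at("GHSQ", "HAFH"), d_acp(),
    d_ks(), d_at("GHSI", "YASH"), d_kr(), d_acp()))
  line <- build_modules(calls)
  tgt <- make_target(c("malonyl", "methylmalonyl"), c("ketone", "hydroxyl"))
  it <- detect_iteration(line$modules, tgt)
  expect_identical(length(it$iterated_modules), 0L)
  expect_identical(it$cycle_to_module, line$modules$module_id)
  expect_identical(it$score, 0)
})

test_that("surplus modules and impossible stutters raise errors", {
  calls <- make_calls("p1", list(
    d_ks(), d_at(), d_acp(), d_ks(), d_at(), d_acp()))
  line <- build_modules(calls)
  tgt1 <- make_target("malonyl", "ketone")
  expect_error(detect_iteration(line$modules, tgt1), "surplus modules")
  # 3 cycles over 2 modules but no two consecutive cycles identical
  tgt3 <- make_target(c("malonyl", "methylmalonyl", "malonyl"),
                      c("ketone", "ketone", "hydroxyl"))
  expect_error(detect_iteration(line$modules, tgt3),
               "no consistent stutter")
})

test_that("a shuffled synthetic line is re-ordered to the planted order", {
  for (seed in c(2L, 5L, 9L)) {
    cfg <- generator_config(seed = seed, proteins = list(
      list(list(at = "methylmalonyl", kr = "B1")),
      list(list(at = "malonyl", kr = "A1"),
           list(at = "malonyl", dh = "active", kr = "B1", er = "tyr")),
      list(list(at = "unusual")),
      list(list(at = "methylmalonyl", dh = "active", kr = "B1"))))
    line <- emit_line(cfg)
    shuffled <- line$proteins[c(3, 1, 4, 2)]
    calls <- classify_domains(scan_domains(shuffled))
    bl <- build_modules(calls)
    tgt <- target_from_truth(line)
    ord <- order_multienzymes(bl, tgt)
    expect_identical(as.character(ord), names(line$proteins))
    expect_identical(attr(ord, "score"), 0)
  }
})

test_that("ordering and iteration agree with the brute-force oracle", {
  set.seed(20240917)
  at_opts <- c("malonyl", "methylmalonyl", "unusual")
  kr_opts <- list(NULL, "A1", "B1", "inactive")
  for (case in 1:12) {
    n_prot <- sample(2:4, 1)
    proteins <- lapply(seq_len(n_prot), function(i) {
      n_mod <- sample(1:2, 1)
      lapply(seq_len(n_mod), function(j) {
        kr <- kr_opts[[sample(length(kr_opts), 1)]]
        dh <- if (!is.null(kr) && kr != "inactive" && runif(1) < 0.5)
          "active" else NULL
        er <- if (!is.null(dh) && runif(1) < 0.5) "tyr" else NULL
        c(list(at = sample(at_opts, 1)),
          if (!is.null(kr)) list(kr = kr),
          if (!is.null(dh)) list(dh = dh),
          if (!is.null(er)) list(er = er))
      })
    })
    cfg <- generator_config(seed = 1000L + case, proteins = proteins)
    line <- emit_line(cfg)
    stutter_at <- sample(nrow(line$modules), 1)
    tgt <- target_from_truth(line, stutter_at = stutter_at)
    calls <- classify_domains(scan_domains(line$proteins))
    bl <- suppressWarnings(build_modules(calls))
    mods <- bl$modules[!bl$modules$malformed, , drop = FALSE]
    ord <- order_multienzymes(bl, tgt)
    it <- attr(ord, "iteration")
    oracle <- oracle_best(mods, tgt, bl$loading$protein, bl$te_protein)
    expect_identical(it$score, oracle$score)
    # the package's chosen assignment is among the oracle optima
    match_found <- any(vapply(oracle$optima, function(o)
      identical(o$modules[o$map], it$cycle_to_module), TRUE))
    expect_true(match_found)
  }
})

test_that("cycle/module conservation and monotone mapping hold", {
  line <- build_modules(ossamycin_domain_calls())
  tgt <- ossamycin_target()
  it <- detect_iteration(line$modules, tgt)
  n_stutter_events <- sum(table(it$cycle_to_module) - 1L)
  expect_identical(nrow(tgt$extensions),
                   nrow(line$modules) + n_stutter_events)
  # monotone: the module sequence follows line order with no back-jumps
  idx <- match(it$cycle_to_module, line$modules$module_id)
  expect_true(all(diff(idx) >= 0))
  expect_true(all(diff(idx) <= 1))
})
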