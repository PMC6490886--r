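test_that("the canonical pathway binds six cluster genes plus the GT", {
  path <- ossamine_pathway()
  expect_identical(path$branch, "canonical")
  expect_identical(length(path$missing_roles), 0L)
  steps <- path$steps
  expect_identical(sum(steps$external), 2L)     # recruited elsewhere
  internal <- steps[!steps$external, ]
  expect_identical(internal$gene_id,
                   c("OssS", "OssT", "OssQ", "OssZ1", "OssJ", "OssI",
                     "OssGT"))
  expect_identical(internal$transform,
                   c("2,3-dehydration", "3-ketoreduction", "3,4-dehydration",
                     "epimerisation", "transamination", "N,N-dimethylation",
                     "glycosyl transfer"))
  expect_identical(steps$product_name[steps$transform == "N,N-dimethylation"],
                   "dTDP-l-ossamine")
  # substrate/product chaining is gap-free
  expect_identical(steps$substrate_name[-1],
                   steps$product_name[-nrow(steps)])
})

test_that("the early-epimerisation branch forms a kedarosamine-type intermediate", {
  path <- ossamine_pathway(branch = "early-epimerisation")
  steps <- path$steps
  epi <- which(steps$transform == "epimerisation")
  dh34 <- which(steps$transform == "3,4-dehydration")
  expect_lt(epi, dh34)
  expect_match(steps$product_name[epi], "kedarosamine")
  expect_identical(steps$substrate_name[-1], steps$product_name[-nrow(steps)])
})

test_that("missing roles are reported as data, not errors", {
  empty <- data.frame(gene_id = character(), name = character(),
                      role = character(), evidence = character())
  path <- reconstruct_pathway(empty)
  expect_identical(sort(path$missing_roles),
                   sort(c("sugar-2,3-dehydratase", "sugar-3-ketoreductase",
                          "sugar-3,4-dehydratase", "sugar-epimerase",
                          "sugar-transaminase", "sugar-N-methyltransferase",
                          "glycosyltransferase")))
  expect_true(all(is.na(path$steps$gene_id[!path$steps$external])))
})

test_that("the glycone formula is the tetradeoxy-dimethylamino hexose", {
  f <- residue_formula(ossamine_pathway())
  expect_identical(format(f), "C8H17NO2")
  expect_identical(unname(unclass(f)["N"]), 1L)
  # independent summation: hexose C6H12O6, minus 4 deoxygenations (one via
  # transamination of the 4-keto), keto/amine redox, plus two N-methyls
  independent <- local({
    x <- c(C = 6, H = 12, O = 6)
    x <- x + c(C = 0, H = -2, O = -1)   # 4,6-dehydration (4-keto-6-deoxy)
    x <- x + c(C = 0, H = 0, O = -1)    # 2-deoxygenation (dehydration+reduction)
    x <- x + c(C = 0, H = 0, O = -1)    # 3-deoxygenation
    x <- x + c(C = 0, H = 3, O = -1) + c(C = 0, H = 0, O = 0)  # transamination
    x <- x + c(C = 2, H = 4, O = 0)     # N,N-dimethylation
    x
  })
  expect_identical(unname(unclass(f)[c("C", "H", "O")]),
                   as.integer(independent[c("C", "H", "O")]))
  # two N-methyl carbons: removing the dimethylation step removes C2H4
  expect_identical(unname(unclass(f)["C"]) - 2L, 6L)
})

test_that("both branches give the same glycone formula (isomers)", {
  f1 <- residue_formula(ossamine_pathway())
  f2 <- residue_formula(ossamine_pathway(branch = "early-epimerisation"))
  expect_identical(unclass(f1), unclass(f2))
  expect_equal(monoisotopic_mass(f1) - monoisotopic_mass(f2), 0)
})

test_that("a graph truncated before transamination is rejected", {
  path <- ossamine_pathway()
  cut <- which(path$steps$transform == "transamination")
  path$steps <- path$steps[seq_len(cut - 1L), ]
  path$transforms <- path$transforms[seq_len(cut - 1L)]
  expect_error(residue_formula(path), "transamination")
})

test_that("DOT export names every step edge", {
  dot <- pathway_dot(ossamine_pathway())
  expect_match(dot, "digraph")
  expect_match(dot, "dTDP-l-ossamine")
  expect_match(dot, "OssS")
})
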