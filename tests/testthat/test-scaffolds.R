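# Bemis-Murcko scaffolds, graph frameworks, macrocycles, diversity.

test_that("scaffold decomposition matches hand-derived structures", {
  expect_equal(bm_scaffold("Cc1ccccc1"), canon("c1ccccc1"))
  expect_equal(bm_scaffold("CCCCCC"), "")
  # 6,7-dimethoxy-4-anilinoquinazoline loses both methoxy side chains
  expect_equal(bm_scaffold("COc1cc2ncnc(Nc3ccccc3)c2cc1OC"),
               canon("c1ccc(Nc2ncnc3ccccc23)cc1"))
  # exocyclic carbonyl double-bonded to the scaffold is retained
  sunitinib_core <- "CCN(CC)CCNC(=O)c1c(C)[nH]c(C=C2C(=O)Nc3ccc(F)cc23)c1C"
  expect_equal(bm_scaffold(sunitinib_core),
               canon("O=C1Nc2ccccc2C1=Cc1ccc[nH]1"))
})

test_that("bm_scaffold is idempotent over a fixture set", {
  for (s in fixture_smiles()) {
    bm <- bm_scaffold(s)
    if (nzchar(bm)) expect_identical(bm_scaffold(bm), bm)
  }
})

test_that("graph frameworks abstract heteroatoms and bond orders", {
  expect_equal(graph_framework(canon("c1ccncc1")), canon("C1CCCCC1"))
  expect_identical(graph_framework(canon("c1ccccc1")),
                   graph_framework(canon("c1ccncc1")))
  expect_equal(graph_framework(""), "")
  # N-phenylquinazolin-4-amine framework has 17 carbons
  gf <- graph_framework(bm_scaffold("COc1cc2ncnc(Nc3ccccc3)c2cc1OC"))
  m <- parse_mol(gf)
  expect_equal(nrow(m$atoms), 17)
  expect_true(all(m$atoms$element == "C"))
  expect_true(all(m$bonds$order == 1))
})

test_that("heteroatom substitution on one skeleton collapses to one framework", {
  variants <- c("c1ccc2ncncc2c1", "c1ccc2ncccc2c1", "c1ccc2ccccc2c1",
                "C1CCc2ccccc2C1", "O=C1CCc2ccccc2C1")
  gfs <- vapply(variants, function(s) graph_framework(bm_scaffold(s)), "")
  # naphthalene-type skeletons all reduce to decalin
  expect_true(all(gfs[1:4] == canon("C1CCC2CCCCC2C1")))
  # the carbonyl variant keeps its retained exocyclic atom
  expect_false(gfs[5] == gfs[1])
})

test_that("macrocycle detection uses strict SSSR ring size", {
  expect_true(detect_macrocycle("C1CCCCCCCCCCCC1"))   # 13-ring
  expect_false(detect_macrocycle("C1CCCCCCCCCCC1"))   # 12-ring boundary
  expect_false(detect_macrocycle("c1ccc2ccccc2c1"))   # envelope not in SSSR
  expect_true(detect_macrocycle("CC1CCCCCCCCCCCC1"))
})

test_that("diversity statistics count unique scaffolds and frameworks", {
  mols <- deduplicate_molecules(standardize_molecules(
    c("Cc1ccccc1", "CCc1ccccc1", "COc1ccccc1", "Brc1ccccc1", "CCCCCC")))
  st <- diversity_stats(mols, similarity = FALSE)
  expect_equal(st$n_molecules, 5)
  expect_equal(st$n_unique_bm, 1)
  expect_equal(st$pct_unique_bm, 20)
  expect_equal(st$n_macrocycles, 0)
  # gf count can never exceed bm count
  lib <- generate_library(library_spec(seed = 12))
  st2 <- diversity_stats(lib$molecules, similarity = FALSE)
  expect_lte(st2$n_unique_gf, st2$n_unique_bm)
  expect_lte(st2$n_unique_bm, st2$n_molecules)
  expect_gte(st2$n_molecules / st2$n_unique_bm, 1)
})

test_that("scaffold matching hits molecules sharing the query scaffold", {
  lib <- deduplicate_molecules(standardize_molecules(
    c("Cc1ccccc1", "CCCCCC", "COc1cc2ncnc(N)c2cc1", "Cc1ccc2ncncc2c1",
      "CN(C)c1ccc2ncncc2c1")))
  hit <- scaffold_match("c1ccccc1", lib, level = "bm")
  expect_equal(hit$per_query$n_hits, 1L)
  # three decorated quinazolines recovered by the quinazoline query
  hitq <- scaffold_match("c1ccc2ncncc2c1", lib, level = "bm")
  expect_equal(hitq$per_query$n_hits, 3L)
  # graph-framework matching is a superset of bm matching
  bm_hits <- scaffold_match("c1ccc2ncncc2c1", lib, "bm")$n_matched
  gf_hits <- scaffold_match("c1ccc2ncncc2c1", lib, "gf")$n_matched
  expect_gte(gf_hits, bm_hits)
})
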