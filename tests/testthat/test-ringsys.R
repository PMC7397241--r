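# Ring-system ensemble extraction and encodings.

test_that("hand-decomposed oracle molecules are encoded exactly", {
  for (case in ring_oracle_cases()) {
    rs <- ring_system_table(case$smiles)
    expected <- tibble::tibble(
      unpositioned = canon(vapply(case$systems, `[`, "", 1)),
      positioned = canon(vapply(case$systems, `[`, "", 2))
    )
    expect_equal(nrow(rs), nrow(expected), info = case$name)
    obs <- dplyr::arrange(rs[, c("unpositioned", "positioned")],
                          .data$unpositioned, .data$positioned)
    exp <- dplyr::arrange(expected, .data$unpositioned, .data$positioned)
    expect_identical(obs$unpositioned, exp$unpositioned, info = case$name)
    expect_identical(obs$positioned, exp$positioned, info = case$name)
  }
})

test_that("ring systems partition exactly the ring atoms of a molecule", {
  for (s in fixture_smiles()) {
    mol <- parse_mol(s)
    systems <- extract_ring_systems(s)
    atoms <- as.integer(unlist(systems))
    expect_equal(anyDuplicated(atoms), 0)
    expect_setequal(atoms, which(mol$atoms$ring))
  }
})

test_that("spiro-fused rings form one system by the atom-fusion rule", {
  rs <- ring_system_table("C1CCC2(CCCCC2)C1")
  expect_equal(nrow(rs), 1)
  expect_equal(rs$n_rings, 2L)
  expect_true(rs$is_bicycle)
})

test_that("bicycle frequency tables count occurrences with tie-broken order", {
  mols <- c("Cc1ccc2ncncc2c1", "CCc1ccc2ncncc2c1", "COc1ccc2ncncc2c1",
            "Cc1ccc2ncccc2c1", "CCc1ccc2ncccc2c1", "Cc1ccc2[nH]ccc2c1",
            "CCCCCC")
  rs <- ring_system_table(mols)
  f <- bicycle_frequency(rs, "unpositioned")
  expect_equal(f$count, c(3L, 2L, 1L))
  expect_equal(f$key[1], canon("c1ccc2ncncc2c1"))
  expect_equal(sum(f$frequency), 1)
  s <- frequency_summary(f)
  expect_equal(s$n_total, 6L)
  expect_equal(s$n_unique, 3L)
  expect_equal(s$n_singletons, 1L)
  # positioned is a refinement: at least as many unique keys
  fp <- bicycle_frequency(rs, "positioned")
  expect_gte(frequency_summary(fp)$n_unique, s$n_unique)
  # no bicycles
  f0 <- bicycle_frequency(ring_system_table("c1ccccc1"), "unpositioned")
  expect_equal(nrow(f0), 0)
  expect_equal(frequency_summary(f0)$n_total, 0L)
})

test_that("bicycle prevalence is the molecule-level fraction", {
  expect_equal(bicycle_prevalence(c("c1ccc2ccccc2c1", "CCCCCC")), 0.5)
  expect_equal(bicycle_prevalence(c("CCCCCC", "CC")), 0)
  # a molecule with two bicycles still counts once
  expect_equal(bicycle_prevalence("c1ccc2ccccc2c1-c1ccc2ccccc2c1"), 1)
  expect_error(bicycle_prevalence(character()), "empty")
})

test_that("stripping positioned encodings reproduces the unpositioned keys", {
  lib <- generate_library(library_spec(seed = 21))
  rs <- ring_system_table(lib$molecules)
  stripped <- vapply(rs$positioned, kinasespace:::strip_positioned,
                     character(1), USE.NAMES = FALSE)
  expect_identical(stripped, rs$unpositioned)
})

test_that("frequencies normalize and totals match extracted systems", {
  lib <- generate_library(library_spec(seed = 22))
  rs <- ring_system_table(lib$molecules)
  f <- bicycle_frequency(rs, "unpositioned", bicycles_only = FALSE)
  expect_equal(frequency_summary(f)$n_total, nrow(rs))
  expect_equal(sum(f$frequency), 1, tolerance = 1e-9)
})
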