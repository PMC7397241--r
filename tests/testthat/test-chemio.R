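# Reading, standardization and deduplication of molecule sets.

test_that("smi/csv/sdf readers preserve records, names and order", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene", "CCN"), smi)
  m <- read_molecules(smi, format = "smi")
  expect_equal(nrow(m), 3)
  expect_equal(m$name, c("ethanol", "benzene", ""))
  expect_equal(m$smiles_input, c("CCO", "c1ccccc1", "CCN"))

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    smiles = c("CCO", "", "c1ccccc1", "CCN", "CCC"),
    cmpd = paste0("m", 1:5), ph = c(4L, 2L, NA, 1L, 3L)), csv)
  m <- read_molecules(csv, format = "csv", name_col = "cmpd",
                      phase_col = "ph", label = "CLINICAL_PKI")
  expect_equal(nrow(m), 5)  # empty cell kept until standardization
  expect_equal(m$phase[1], 4L)
  expect_true(all(m$dataset_label == "CLINICAL_PKI"))
  std <- deduplicate_molecules(standardize_molecules(m))
  expect_equal(nrow(std), 4)
  expect_equal(standardization_report(std)$n_empty_or_unparseable, 1)

  sdf <- withr::local_tempfile(fileext = ".sdf")
  block <- kinasespace:::ob_convert("CCO first\nCCN second\n", "SMI", "SDF")
  writeLines(block, sdf)
  m <- read_molecules(sdf, format = "sdf")
  expect_equal(nrow(m), 2)
  expect_equal(m$name, c("first", "second"))

  expect_error(read_molecules("does/not/exist.smi", "smi"), "not found")
  expect_error(read_molecules(csv, format = "csv", smiles_col = "nope"),
               "not found")
})

test_that("standardization keeps the largest neutral organic fragment", {
  # already-standard structure unchanged
  expect_equal(standardize_molecules("CCO")$smiles_std, "CCO")
  # bromide counter-ion on a charged parent is removed entirely
  std <- standardize_molecules("C[n+]1ccccc1CCO.[Br-]")$smiles_std
  expect_false(grepl("Br", std))
  expect_false(grepl("\\.", std))
  # sodium glycinate becomes neutral glycine
  std <- standardize_molecules("C(C(=O)[O-])N.[Na+]")$smiles_std
  expect_equal(std, kinasespace:::ob_canonical("NCC(=O)O"))
  # salt with no organic fragment is flagged invalid
  expect_true(is.na(standardize_molecules("[Na+].[Cl-]")$smiles_std))
  # unparseable and empty records flagged, not fatal
  out <- standardize_molecules(c("C1CC", "", "CCO"))
  expect_equal(is.na(out$smiles_std), c(TRUE, TRUE, FALSE))
})

test_that("standardization is idempotent on a synthetic library", {
  mols <- generate_library(library_spec(
    scaffold_pool = default_scaffold_pool()[c(1, 4, 6), ] |>
      dplyr::mutate(multiplicity = c(5L, 3L, 4L)),
    seed = 303))$molecules
  once <- standardize_molecules(mols$smiles_std)$smiles_std
  twice <- standardize_molecules(once)$smiles_std
  expect_identical(once, twice)
})

test_that("deduplication keeps first occurrence per InChIKey", {
  mols <- standardize_molecules(c("CCO", "OCC", "CC(C)O", "CCO"))
  out <- deduplicate_molecules(mols)
  expect_equal(nrow(out), 2)  # CCO == OCC, duplicate CCO dropped
  rep <- standardization_report(out)
  expect_equal(rep$n_duplicates_removed, 2)
  expect_equal(rep$n_output,
               rep$n_input - rep$n_empty_or_unparseable -
                 rep$n_duplicates_removed)
  # stereoisomers carry distinct keys and are both kept
  st <- deduplicate_molecules(standardize_molecules(
    c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O")))
  expect_equal(nrow(st), 2)
  # empty input
  empty <- deduplicate_molecules(standardize_molecules(character()))
  expect_equal(nrow(empty), 0)
  expect_equal(standardization_report(empty)$n_input, 0)
})

test_that("dedup output size equals the number of distinct InChIKeys", {
  mols <- standardize_molecules(fixture_smiles())
  out <- deduplicate_molecules(mols)
  expect_equal(nrow(out), dplyr::n_distinct(mols$inchikey[!is.na(mols$inchikey)]))
})

test_that("write/read round trip preserves structures and labels", {
  mols <- fixture_molecules()
  mols$dataset_label <- rep(c("APPROVED_PKI", "CLINICAL_PKI"),
                            length.out = nrow(mols))
  path <- withr::local_tempfile(fileext = ".csv")
  write_molecules(mols, path)
  back <- read_molecules(path, format = "csv", smiles_col = "smiles_std",
                         name_col = "name")
  expect_equal(back$smiles_input, mols$smiles_std)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(raw$dataset_label, mols$dataset_label)
  expect_identical(raw$inchikey, mols$inchikey)
})
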