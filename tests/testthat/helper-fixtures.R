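# Shared fixtures: hand-decomposed ring-system oracle molecules and small
# reusable molecule sets. Expected encodings are written by hand from the
# structures and only normalized (canonicalized) before comparison.

canon <- function(x) vapply(x, function(s) kinasespace:::ob_canonical(s),
                            character(1), USE.NAMES = FALSE)

# Each row: molecule SMILES plus the hand-derived ring systems as a list
# of c(unpositioned, positioned) pairs (one pair per fused ring system).
ring_oracle_cases <- function() {
  list(
    list(name = "toluene", smiles = "Cc1ccccc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"))),
    list(name = "acetophenone", smiles = "CC(=O)c1ccccc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"))),
    list(name = "benzaldehyde", smiles = "O=Cc1ccccc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"))),
    list(name = "styrene", smiles = "C=Cc1ccccc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"))),
    list(name = "benzyl chloride", smiles = "ClCc1ccccc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"))),
    list(name = "trifluoromethylbenzene", smiles = "FC(F)(F)c1ccccc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"))),
    list(name = "4-bromoanisole", smiles = "COc1ccc(Br)cc1",
         systems = list(c("c1ccccc1", "[1*]c1ccc([4*])cc1"))),
    list(name = "p-fluorotoluene", smiles = "Cc1ccc(F)cc1",
         systems = list(c("c1ccccc1", "[1*]c1ccc([4*])cc1"))),
    list(name = "biphenyl", smiles = "c1ccc(-c2ccccc2)cc1",
         systems = list(c("c1ccccc1", "[3*]c1ccccc1"),
                        c("c1ccccc1", "[3*]c1ccccc1"))),
    list(name = "benzophenone", smiles = "O=C(c1ccccc1)c1ccccc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"),
                        c("c1ccccc1", "[1*]c1ccccc1"))),
    list(name = "cyclohexylbenzene", smiles = "C1CCC(CC1)c1ccccc1",
         systems = list(c("C1CCCCC1", "[3*]C1CCCCC1"),
                        c("c1ccccc1", "[2*]c1ccccc1"))),
    list(name = "4,4'-bipyridine", smiles = "c1cc(-c2ccncc2)ccn1",
         systems = list(c("c1ccncc1", "[3*]c1ccncc1"),
                        c("c1ccncc1", "[3*]c1ccncc1"))),
    list(name = "benzene", smiles = "c1ccccc1",
         systems = list(c("c1ccccc1", "c1ccccc1"))),
    list(name = "naphthalene", smiles = "c1ccc2ccccc2c1",
         systems = list(c("c1ccc2ccccc2c1", "c1ccc2ccccc2c1"))),
    list(name = "2-methylnaphthalene", smiles = "Cc1ccc2ccccc2c1",
         systems = list(c("c1ccc2ccccc2c1", "[1*]c1ccc2ccccc2c1"))),
    list(name = "anthracene", smiles = "c1ccc2cc3ccccc3cc2c1",
         systems = list(c("c1ccc2cc3ccccc3cc2c1",
                          "c1ccc2cc3ccccc3cc2c1"))),
    list(name = "fluorene", smiles = "C1c2ccccc2-c2ccccc21",
         systems = list(c("C1c2ccccc2-c2ccccc21", "C1c2ccccc2-c2ccccc21"))),
    list(name = "adamantane", smiles = "C1C2CC3CC1CC(C2)C3",
         systems = list(c("C1C2CC3CC1CC(C2)C3", "C1C2CC3CC1CC(C2)C3"))),
    list(name = "spiro[4.5]decane", smiles = "C1CCC2(CCCCC2)C1",
         systems = list(c("C1CCC2(CCCCC2)C1", "C1CCC2(CCCCC2)C1"))),
    list(name = "cyclotridecane", smiles = "C1CCCCCCCCCCCC1",
         systems = list(c("C1CCCCCCCCCCCC1", "C1CCCCCCCCCCCC1"))),
    list(name = "methylcyclotridecane", smiles = "CC1CCCCCCCCCCCC1",
         systems = list(c("C1CCCCCCCCCCCC1", "[1*]C1CCCCCCCCCCCC1"))),
    list(name = "quinazoline", smiles = "c1ccc2ncncc2c1",
         systems = list(c("c1ccc2ncncc2c1", "c1ccc2ncncc2c1"))),
    list(name = "indole", smiles = "c1ccc2[nH]ccc2c1",
         systems = list(c("c1ccc2[nH]ccc2c1", "c1ccc2[nH]ccc2c1"))),
    list(name = "1-methylindole", smiles = "Cn1ccc2ccccc21",
         systems = list(c("c1ccc2[nH]ccc2c1", "[1*]n1ccc2ccccc21"))),
    list(name = "oxindole", smiles = "O=C1Cc2ccccc2N1",
         systems = list(c("C1Cc2ccccc2N1", "O=C1Cc2ccccc2N1"))),
    list(name = "1-methyloxindole", smiles = "CN1C(=O)Cc2ccccc21",
         systems = list(c("C1Cc2ccccc2N1", "[1*]N1C(=O)Cc2ccccc21"))),
    list(name = "quinolin-2(1H)-one", smiles = "O=C1C=Cc2ccccc2N1",
         systems = list(c("C1C=Cc2ccccc2N1", "O=C1C=Cc2ccccc2N1"))),
    list(name = "4-anilinoquinazoline", smiles = "c1ccc(Nc2ncnc3ccccc23)cc1",
         systems = list(c("c1ccccc1", "[1*]c1ccccc1"),
                        c("c1ccc2ncncc2c1", "[1*]c1ncnc2ccccc12"))),
    list(name = "4-phenylquinazoline", smiles = "c1ccc(-c2ncnc3ccccc23)cc1",
         systems = list(c("c1ccccc1", "[3*]c1ccccc1"),
                        c("c1ccc2ncncc2c1", "[3*]c1ncnc2ccccc12"))),
    list(name = "gefitinib-like quinazoline",
         smiles = "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1",
         systems = list(
           c("c1ccc2ncncc2c1", "[1*]c1cc2ncnc([1*])c2cc1[1*]"),
           c("c1ccccc1", "[1*]c1ccc([4*])c([4*])c1"),
           c("C1COCCN1", "[1*]N1CCOCC1")))
  )
}

# A small, diverse standardized molecule set used by property tests.
fixture_smiles <- function() {
  c("Cc1ccccc1", "CC(=O)c1ccccc1", "COc1ccc(Br)cc1",
    "c1ccc(-c2ccccc2)cc1", "Cc1ccc2ccccc2c1", "O=C1Cc2ccccc2N1",
    "C1CCCCCCCCCCCC1", "c1ccc2ncncc2c1", "CCN(CC)CCO",
    "COc1cc2ncnc(Nc3ccccc3)c2cc1OC", "CC(N)C(=O)O",
    "c1ccc2[nH]ccc2c1", "C1CCC2(CCCCC2)C1", "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    "O=C(O)c1ccccc1O", "Clc1ccccc1Cl", "c1ccncc1", "C1COCCN1",
    "CC(=O)Nc1ccc(O)cc1", "c1cnc2[nH]ccc2c1")
}

fixture_molecules <- function() {
  deduplicate_molecules(standardize_molecules(fixture_smiles()))
}

expect_same_counts <- function(observed, expected) {
  expect_identical(observed$key, expected$key)
  expect_identical(as.integer(observed$count), as.integer(expected$count))
}
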