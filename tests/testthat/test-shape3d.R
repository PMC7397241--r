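# Conformer embedding contract and PMI computation.

# Independent inertia oracle: explicit textbook formulas for the moment
# and product components, assembled atom by atom.
oracle_inertia_moments <- function(coords, masses) {
  x <- coords$x; y <- coords$y; z <- coords$z; m <- masses
  cx <- sum(m * x) / sum(m); cy <- sum(m * y) / sum(m); cz <- sum(m * z) / sum(m)
  x <- x - cx; y <- y - cy; z <- z - cz
  ixx <- sum(m * (y^2 + z^2)); iyy <- sum(m * (x^2 + z^2))
  izz <- sum(m * (x^2 + y^2))
  ixy <- -sum(m * x * y); ixz <- -sum(m * x * z); iyz <- -sum(m * y * z)
  tensor <- matrix(c(ixx, ixy, ixz, ixy, iyy, iyz, ixz, iyz, izz), 3, 3)
  sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
}

test_that("embedding is deterministic for a given structure and seed", {
  smi <- "COc1cc2ncnc(Nc3ccccc3)c2cc1OC"
  a <- embed_conformers(smi, n_confs = 3, seed = 7)
  b <- embed_conformers(smi, n_confs = 3, seed = 7)
  expect_equal(a$energy, b$energy)
  expect_identical(a$coords[[1]], b$coords[[1]])
  expect_equal(a$status, "ok")
})

test_that("benzene embeds as a planar conformer", {
  emb <- embed_conformers("c1ccccc1", n_confs = 1, seed = 1)
  cc <- emb$coords[[1]]
  xyz <- as.matrix(cc[, c("x", "y", "z")])
  centered <- sweep(xyz, 2, colMeans(xyz))
  # smallest principal axis spread = out-of-plane deviation
  dev <- sqrt(min(eigen(crossprod(centered))$values) / nrow(xyz))
  expect_lt(dev, 0.05)
})

test_that("embedding failures are reported per molecule, not fatally", {
  emb <- embed_conformers(c("C1CC", "CCO"), n_confs = 1, seed = 1)
  expect_equal(emb$status, c("fail", "ok"))
  tb <- pmi_table(tibble::tibble(id = c("bad", "good"),
                                 smiles_std = c("C1CC", "CCO")),
                  n_confs = 1, seed = 1)
  expect_setequal(tb$id, c("good", "REF_ROD", "REF_DISC", "REF_SPHERE"))
})

test_that("reference molecules sit at the triangle vertices", {
  tb <- pmi_table(tibble::tibble(id = character(), smiles_std = character()),
                  n_confs = 3, seed = 42)
  expect_equal(nrow(tb), 3)
  rod <- tb[tb$id == "REF_ROD", ]
  disc <- tb[tb$id == "REF_DISC", ]
  sph <- tb[tb$id == "REF_SPHERE", ]
  expect_equal(c(rod$NPR1, rod$NPR2), c(0, 1), tolerance = 0.03)
  expect_equal(c(disc$NPR1, disc$NPR2), c(0.5, 0.5), tolerance = 0.03)
  expect_equal(c(sph$NPR1, sph$NPR2), c(1, 1), tolerance = 0.05)
})

test_that("pmi_point matches the brute-force tensor oracle", {
  emb <- embed_conformers(c("CCO", "c1ccccc1", "CC(C)CC(N)C(=O)O",
                            "C1CCCCCCCCCCCC1"), n_confs = 1, seed = 5)
  for (cc in emb$coords) {
    pt <- pmi_point(cc, cc$mass)
    ev <- oracle_inertia_moments(cc, cc$mass)
    expect_equal(c(pt$I1, pt$I2, pt$I3), ev, tolerance = 1e-8)
  }
})

test_that("PMI is invariant under rigid rotation and translation", {
  emb <- embed_conformers("CC(C)c1ccc2ncncc2c1", n_confs = 1, seed = 9)
  cc <- emb$coords[[1]]
  base <- pmi_point(cc, cc$mass)
  set.seed(13)
  for (r in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    xyz <- as.matrix(cc[, c("x", "y", "z")]) %*% q
    xyz <- sweep(xyz, 2, rnorm(3, sd = 10), "+")
    moved <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    pt <- pmi_point(moved, cc$mass)
    expect_equal(c(pt$I1, pt$I2, pt$I3), c(base$I1, base$I2, base$I3),
                 tolerance = 1e-8)
  }
})

test_that("degenerate geometries are rejected", {
  flat <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(0, 0))
  expect_error(pmi_point(flat, c(12, 12)), "coincident")
})

test_that("every PMI point satisfies the triangle invariants", {
  mols <- fixture_molecules()
  tb <- pmi_table(mols, n_confs = 2, seed = 17)
  expect_true(all(tb$I1 <= tb$I2 + 1e-9 & tb$I2 <= tb$I3 + 1e-9))
  expect_true(all(tb$NPR1 >= -1e-6 & tb$NPR2 <= 1 + 1e-6))
  expect_true(all(tb$NPR1 + tb$NPR2 >= 1 - 1e-6))
  expect_true(all(tb$NPR1 <= tb$NPR2 + 1e-9))
})
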