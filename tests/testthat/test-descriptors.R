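# Descriptor panel, rule profiling and guideline derivation.

test_that("descriptor panel matches hand-derived values", {
  d <- compute_descriptors(c("c1ccccc1", "CCCCCC", "CC(N)C(=O)O"))
  bz <- d[1, ]
  expect_equal(bz$HBA, 0)
  expect_equal(bz$HBD, 0)
  expect_equal(bz$NRB, 0)
  expect_equal(bz$NAR, 1)
  expect_equal(bz$TPSA, 0)
  expect_equal(bz$NCA, 0)
  expect_equal(bz$FCSP3, 0)
  expect_equal(bz$MW, 78.11, tolerance = 1e-3)
  hex <- d[2, ]
  expect_equal(hex$NAR, 0)
  expect_equal(hex$NRB, 3)  # three non-terminal acyclic single bonds
  expect_equal(hex$FCSP3, 1)
  ala <- d[3, ]
  expect_equal(ala$NCA, 1)
  expect_equal(ala$HBA, 3)   # N + 2 O
  expect_equal(ala$HBD, 3)   # NH2 + OH
  expect_equal(ala$MQN8, 1)  # acyclic N
  expect_equal(ala$MQN10, 2) # acyclic O
})

test_that("rule profile equals a brute-force re-evaluation", {
  lib <- generate_library(library_spec(seed = 71))
  d <- compute_descriptors(lib$molecules)
  prof <- rule_profile(d)
  # independent oracle: evaluate each inequality directly
  oracle_lip <- (d$MW > 500) + (d$ClogP > 5) + (d$HBA > 10) + (d$HBD > 5)
  oracle_veb <- (d$TPSA > 140) + (d$NRB > 10)
  expect_identical(prof$lipinski_violations, as.integer(oracle_lip))
  expect_identical(prof$veber_violations, as.integer(oracle_veb))
})

test_that("violation thresholds are strict inequalities", {
  d <- tibble::tibble(MW = c(600, 0, 500), ClogP = c(6, 0, 5),
                      HBA = c(3, 0, 10), HBD = c(1, 0, 5),
                      TPSA = c(0, 0, 140), NRB = c(0, 0, 10))
  p <- rule_profile(d)
  expect_equal(p$lipinski_violations, c(2L, 0L, 0L))
  expect_equal(p$veber_violations, c(0L, 0L, 0L))
})

test_that("violation distribution partitions the dataset", {
  d <- tibble::tibble(MW = c(1, 1, 600, 600), ClogP = c(0, 0, 0, 6),
                      HBA = 0, HBD = 0, TPSA = 0, NRB = 0)
  v <- violation_distribution(d)
  expect_equal(v$class, c("0", "1", "2", ">2"))
  expect_equal(v$n, c(2L, 1L, 1L, 0L))
  expect_equal(sum(v$n), nrow(d))
  expect_equal(sum(v$percent), 100)
  expect_error(violation_distribution(d[0, ]), "empty")
  # planted violation classes are recovered exactly
  planted <- plant_violation_table(c("0" = 7, "1" = 4, "2" = 2, ">2" = 3),
                                   seed = 5)
  expect_equal(violation_distribution(planted)$n, c(7L, 4L, 2L, 3L))
})

test_that("guideline ranges follow the closed-form sample statistics", {
  d <- tibble::tibble(HBA = c(1, 2, 3, 4, 5))
  g <- derive_guidelines(d)
  expect_equal(g$mean, 3)
  expect_equal(g$sd, 1.5811, tolerance = 1e-4)
  expect_equal(g$lower, max(0, 3 - 2 * stats::sd(1:5)))
  expect_equal(g$upper, 3 + 2 * stats::sd(1:5))
  # constant column collapses to a point
  g0 <- derive_guidelines(tibble::tibble(MW = rep(10, 4)))
  expect_equal(g0$sd, 0)
  expect_equal(g0$lower, g0$upper)
  expect_error(derive_guidelines(tibble::tibble(MW = 1)), "two molecules")
})

test_that("count-descriptor lower bounds are clamped at zero", {
  g <- derive_guidelines(tibble::tibble(NCA = c(0, 0, 1, 0, 2)))
  expect_gte(g$lower, 0)
  expect_equal(g$lower_print, 0)
})

test_that("guideline coverage approaches the two-sigma normal mass", {
  x <- generate_descriptor_table(10000, means = c(MW = 100),
                                 sds = c(MW = 10), seed = 99)
  g <- derive_guidelines(x)
  cov <- guideline_coverage(x$MW, g[g$descriptor == "MW", ])
  expect_equal(cov, 0.954, tolerance = 0.006 / 0.954)
})
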