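# Correlation-metric PCA: variance decomposition, contributions,
# correlation circle, class ellipses.

test_that("perfectly correlated variables collapse onto one component", {
  set.seed(1)
  x <- tibble::tibble(a = rnorm(50))
  x$b <- 2 * x$a
  fit <- fit_pca(x, variables = c("a", "b"))
  expect_equal(fit$explained_ratio[1], 1, tolerance = 1e-12)
  cc <- correlation_circle(fit)
  expect_equal(abs(cc$x), c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("eigenvalues match an independent eigendecomposition", {
  p <- 10
  cor_mat <- outer(1:p, 1:p, function(i, j) 0.5^abs(i - j))
  means <- stats::setNames(rep(c(100, 5), length.out = p), paste0("V", 1:p))
  sds <- stats::setNames(rep(c(10, 1), length.out = p), paste0("V", 1:p))
  x <- generate_descriptor_table(10000, means, sds, cor_mat, seed = 42)
  fit <- fit_pca(x, variables = names(means))
  # oracle: eigendecomposition of the sample correlation matrix
  oracle <- eigen(stats::cor(as.matrix(x)), symmetric = TRUE)
  expect_equal(fit$eigenvalues, oracle$values, tolerance = 1e-6)
  for (k in 1:p) {
    v <- oracle$vectors[, k]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(fit$loadings[, k]), v, tolerance = 1e-6)
  }
  # sampling brings eigenvalues near the population decomposition
  pop <- eigen(cor_mat, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$eigenvalues, pop, tolerance = 0.05)
})

test_that("contributions are squared-loading percentages summing to 100", {
  lib <- generate_library(library_spec(seed = 31))
  d <- compute_descriptors(lib$molecules)
  vars <- intersect(pca_descriptor_names(), names(d))
  vars <- vars[vapply(d[vars], stats::sd, 0) > 0]
  fit <- fit_pca(d, variables = vars)
  expect_equal(unname(colSums(fit$contributions)),
               rep(100, ncol(fit$contributions)))
  # independent formula path
  alt <- 100 * fit$loadings^2 / matrix(colSums(fit$loadings^2),
                                       nrow(fit$loadings),
                                       ncol(fit$loadings), byrow = TRUE)
  expect_equal(fit$contributions, alt, tolerance = 1e-12)
  expect_true(all(diff(fit$explained_ratio) <= 1e-12))
  expect_equal(sum(fit$explained_ratio), 1, tolerance = 1e-12)
})

test_that("projection is exact on training data and centered at the mean", {
  x <- generate_descriptor_table(
    200, c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 0.5), seed = 7)
  fit <- fit_pca(x, variables = c("a", "b", "c"))
  proj <- project_pca(fit, x)
  expect_equal(as.matrix(proj$scores[, c("PC1", "PC2", "PC3")]),
               unname(fit$scores), ignore_attr = TRUE, tolerance = 1e-12)
  center <- tibble::tibble(a = fit$means["a"], b = fit$means["b"],
                           c = fit$means["c"])
  sc <- project_pca(fit, center)$scores
  expect_equal(unlist(sc[1, c("PC1", "PC2", "PC3")]), c(PC1 = 0, PC2 = 0,
                                                        PC3 = 0),
               tolerance = 1e-12)
  expect_error(project_pca(fit, x[, 1:2]), "absent")
})

test_that("standardized data are reconstructed from all components", {
  x <- generate_descriptor_table(
    100, c(a = 0, b = 0, c = 0, d = 0), c(a = 1, b = 2, c = 3, d = 4),
    seed = 3)
  fit <- fit_pca(x, variables = letters[1:4])
  z <- scale(as.matrix(x))
  recon <- fit$scores %*% t(fit$loadings)
  expect_equal(recon, z, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("95% ellipses cover the nominal mass of an isotropic class", {
  n <- 10000
  x <- generate_descriptor_table(
    n, c(a = 0, b = 0), c(a = 1, b = 1), seed = 11)
  x$dataset_label <- "CLASS_A"
  fit <- fit_pca(x, variables = c("a", "b"))
  proj <- project_pca(fit, x)
  ell <- proj$ellipses[proj$ellipses$class == "CLASS_A", ]
  inside <- in_ellipse(proj$scores$PC1, proj$scores$PC2, ell)
  expect_equal(mean(inside), 0.95, tolerance = 0.007 / 0.95)
})

test_that("constant variables are rejected by name", {
  set.seed(2)
  x <- tibble::tibble(a = rnorm(20), b = 1)
  expect_error(fit_pca(x, variables = c("a", "b")), "b")
})

test_that("tidy and glance summarize the fit", {
  x <- generate_descriptor_table(50, c(a = 0, b = 0, c = 0),
                                 c(a = 1, b = 1, c = 1), seed = 2)
  fit <- fit_pca(x, variables = c("a", "b", "c"))
  ev <- tidy(fit, "eigenvalues")
  expect_equal(nrow(ev), 3)
  expect_equal(ev$cumulative[3], 1, tolerance = 1e-12)
  ld <- tidy(fit, "loadings")
  expect_equal(nrow(ld), 9)
  g <- glance(fit)
  expect_equal(g$n_variables, 3)
  expect_equal(g$pct_pc1 + g$pct_pc2 + g$pct_pc3, 100, tolerance = 1e-9)
})
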