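# Correlation-metric PCA of the descriptor panel: explained variance,
# variable contributions, correlation-circle coordinates and 95% class
# ellipses in the score plane.

#' Fit a PCA on descriptor columns
#'
#' Variables are centered and scaled to unit variance (correlation-metric
#' PCA) before the decomposition. Component signs follow a fixed
#' convention: within each component the largest-magnitude loading is
#' positive. Contribution of variable j to component k is
#' `100 * loading[j,k]^2 / sum_j loading[j,k]^2`.
#'
#' @param data tibble of descriptors (e.g. [compute_descriptors()] output).
#' @param variables descriptor columns to use; defaults to the
#'   ten-descriptor panel of [pca_descriptor_names()] intersected with the
#'   available columns.
#' @return an object of class `kin_pca` with elements `means`, `sds`,
#'   `loadings`, `eigenvalues`, `explained_ratio`, `contributions`,
#'   `scores` (training scores), `variables`.
#' @export
fit_pca <- function(data, variables = NULL) {
  d <- tibble::as_tibble(data)
  if (is.null(variables)) {
    variables <- intersect(pca_descriptor_names(), names(d))
    if (length(variables) == 0) {
      variables <- names(d)[vapply(d, is.numeric, logical(1))]
    }
  }
  stopifnot(all(variables %in% names(d)))
  x <- as.matrix(d[, variables])
  if (anyNA(x)) stop("missing values in PCA variables", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # deterministic sign convention
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  fit$rotation <- sweep(fit$rotation, 2, flip, "*")
  fit$x <- sweep(fit$x, 2, flip, "*")
  contrib <- sweep(fit$rotation^2, 2, colSums(fit$rotation^2), "/") * 100
  structure(
    list(
      means = fit$center,
      sds = fit$scale,
      loadings = fit$rotation,
      eigenvalues = fit$sdev^2,
      explained_ratio = fit$sdev^2 / sum(fit$sdev^2),
      contributions = contrib,
      scores = fit$x,
      variables = variables
    ),
    class = "kin_pca"
  )
}

#' @export
print.kin_pca <- function(x, ...) {
  cat("Correlation-metric PCA:", length(x$variables), "variables,",
      length(x$eigenvalues), "components\n")
  pct <- round(100 * x$explained_ratio, 1)
  cat("Explained variance (%):", paste(pct, collapse = ", "), "\n")
  invisible(x)
}

#' Project molecules into a fitted PCA space
#'
#' Scores are the standardized data multiplied by the loadings. When a
#' class column is given, a 95% normal (chi-square, 2 df) ellipse is
#' estimated for each class in the PC1/PC2 plane.
#'
#' @param model a [fit_pca()] object.
#' @param data tibble containing the model's variables (and optionally
#'   `id` and the class column).
#' @param class_col name of the class column (default `dataset_label`
#'   when present).
#' @param level ellipse confidence level.
#' @return list with `scores` (tibble: id, class, PC1..PCk) and
#'   `ellipses` (tibble: class, center, covariance entries, level).
#' @export
project_pca <- function(model, data, class_col = NULL, level = 0.95) {
  stopifnot(inherits(model, "kin_pca"))
  d <- tibble::as_tibble(data)
  missing_vars <- setdiff(model$variables, names(d))
  if (length(missing_vars) > 0) {
    stop("variables absent from data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(d[, model$variables])
  z <- sweep(sweep(x, 2, model$means), 2, model$sds, "/")
  sc <- z %*% model$loadings
  scores <- tibble::as_tibble(sc)
  if ("id" %in% names(d)) scores <- dplyr::bind_cols(d["id"], scores)
  if (is.null(class_col) && "dataset_label" %in% names(d)) {
    class_col <- "dataset_label"
  }
  ellipses <- NULL
  if (!is.null(class_col) && class_col %in% names(d)) {
    scores$class <- as.character(d[[class_col]])
    ellipses <- purrr::map_dfr(split(seq_len(nrow(sc)), scores$class),
                               function(rows) {
      if (length(rows) < 3) return(NULL)
      s2 <- sc[rows, 1:2, drop = FALSE]
      ctr <- colMeans(s2)
      cv <- stats::cov(s2)
      tibble::tibble(
        class = scores$class[rows[1]],
        center_x = ctr[1], center_y = ctr[2],
        var_x = cv[1, 1], var_y = cv[2, 2], cov_xy = cv[1, 2],
        level = level
      )
    })
  }
  list(scores = scores, ellipses = ellipses)
}

#' Correlation-circle coordinates
#'
#' Coordinates of each variable on two components are the correlations
#' between the variable and the component scores; all points lie within
#' the unit disk.
#'
#' @param model a [fit_pca()] object.
#' @param components indices of the two components (default PC1/PC2).
#' @return tibble with `variable`, `x`, `y`.
#' @export
correlation_circle <- function(model, components = c(1, 2)) {
  stopifnot(inherits(model, "kin_pca"), length(components) == 2)
  if (length(model$eigenvalues) < max(components)) {
    stop("model has fewer components than requested", call. = FALSE)
  }
  sdev <- sqrt(model$eigenvalues)
  tibble::tibble(
    variable = rownames(model$loadings),
    x = model$loadings[, components[1]] * sdev[components[1]],
    y = model$loadings[, components[2]] * sdev[components[2]]
  )
}

#' Test whether points fall inside a class ellipse
#'
#' @param x,y point coordinates in the PC1/PC2 plane.
#' @param ellipse one row of the `ellipses` table from [project_pca()].
#' @return logical vector.
#' @export
in_ellipse <- function(x, y, ellipse) {
  s <- matrix(c(ellipse$var_x, ellipse$cov_xy, ellipse$cov_xy, ellipse$var_y),
              2, 2)
  si <- solve(s)
  dx <- cbind(x - ellipse$center_x, y - ellipse$center_y)
  d2 <- rowSums((dx %*% si) * dx)
  d2 <= stats::qchisq(ellipse$level, df = 2)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PCA
#'
#' @param x a `kin_pca` object.
#' @param matrix which quantity to return: `"loadings"`,
#'   `"contributions"` (percent) or `"eigenvalues"`.
#' @param ... unused.
#' @return a long tibble.
#' @export
tidy.kin_pca <- function(x, matrix = c("loadings", "contributions",
                                       "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      component = seq_along(x$eigenvalues),
      eigenvalue = x$eigenvalues,
      explained_ratio = x$explained_ratio,
      cumulative = cumsum(x$explained_ratio)
    ))
  }
  m <- x[[matrix]]
  out <- tibble::as_tibble(m, rownames = "variable")
  tidyr::pivot_longer(out, -"variable", names_to = "component",
                      values_to = sub("s$", "", matrix))
}

#' One-row summary of a fitted PCA
#'
#' @param x a `kin_pca` object.
#' @param ... unused.
#' @return tibble with variable/component counts and the variance
#'   explained by the first three components.
#' @export
glance.kin_pca <- function(x, ...) {
  er <- x$explained_ratio
  tibble::tibble(
    n_variables = length(x$variables),
    n_components = length(er),
    pct_pc1 = 100 * er[1],
    pct_pc2 = 100 * er[2],
    pct_pc3 = if (length(er) >= 3) 100 * er[3] else NA_real_
  )
}
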