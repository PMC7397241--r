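# Pairwise fingerprint similarity statistics and Butina clustering.

tanimoto_matrix_block <- function(fp_a, fp_b) {
  # fp_*: logical matrices (rows = molecules)
  a <- fp_a * 1
  b <- fp_b * 1
  common <- a %*% t(b)
  on_a <- rowSums(a)
  on_b <- rowSums(b)
  denom <- outer(on_a, on_b, "+") - common
  sim <- ifelse(denom == 0, 1, common / denom)
  sim
}

#' Pairwise Tanimoto similarity statistics
#'
#' Computes the mean and sample standard deviation of the Tanimoto
#' coefficient over all unordered molecule pairs, streaming over row
#' blocks so that the full pair matrix is never held in memory.
#'
#' @param mols molecule tibble with `smiles_std` (or a character vector).
#' @param fingerprint `"maccs"` (166-bit structural keys) or `"ecfp4"`
#'   (circular, radius 2).
#' @param block_size rows per streamed block.
#' @return one-row tibble with `n_pairs`, `mean`, `sd`, `fingerprint`.
#' @export
pairwise_similarity <- function(mols, fingerprint = c("maccs", "ecfp4"),
                                block_size = 256L) {
  fingerprint <- match.arg(fingerprint)
  smiles <- if (is.character(mols)) mols else mols$smiles_std
  n <- length(smiles)
  if (n < 2) stop("similarity requires at least two molecules", call. = FALSE)
  fp <- ob_fingerprints(smiles, fingerprint)
  # running (streaming) moments over pair similarities
  count <- 0
  total <- 0
  total_sq <- 0
  starts <- seq(1L, n, by = block_size)
  for (si in starts) {
    ri <- si:min(si + block_size - 1L, n)
    for (sj in starts[starts >= si]) {
      rj <- sj:min(sj + block_size - 1L, n)
      sim <- tanimoto_matrix_block(fp[ri, , drop = FALSE],
                                   fp[rj, , drop = FALSE])
      if (si == sj) {
        vals <- sim[upper.tri(sim)]
      } else {
        vals <- as.vector(sim)
      }
      count <- count + length(vals)
      total <- total + sum(vals)
      total_sq <- total_sq + sum(vals^2)
    }
  }
  mean_sim <- total / count
  # a single pair has no dispersion; report 0 rather than NaN
  var_sim <- if (count > 1) {
    (total_sq - count * mean_sim^2) / (count - 1)
  } else 0
  tibble::tibble(
    n_pairs = count,
    mean = mean_sim,
    sd = sqrt(max(0, var_sim)),
    fingerprint = fingerprint
  )
}

#' Butina (leader) clustering
#'
#' Sphere-exclusion clustering at a Tanimoto distance threshold using
#' ECFP4 circular fingerprints: molecules are ranked by neighbor count,
#' the best-connected unassigned molecule becomes a centroid, and its
#' unassigned neighbors join its cluster. Deterministic for a given input
#' order (ties broken by input position).
#'
#' @param mols molecule tibble with `id` and `smiles_std` (or a character
#'   vector of SMILES).
#' @param threshold Tanimoto distance threshold in `[0, 1]`: molecules at
#'   distance `<= threshold` from a centroid are neighbors.
#' @param fingerprint fingerprint kind, see [pairwise_similarity()].
#' @return tibble with `molecule_id`, `cluster_id`, `is_centroid`.
#' @export
cluster_butina <- function(mols, threshold = 0.6,
                           fingerprint = c("ecfp4", "maccs")) {
  fingerprint <- match.arg(fingerprint)
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  n <- nrow(mols)
  stopifnot(n >= 1)
  if (n == 1) {
    return(tibble::tibble(molecule_id = mols$id, cluster_id = 1L,
                          is_centroid = TRUE))
  }
  fp <- ob_fingerprints(mols$smiles_std, fingerprint)
  sim <- tanimoto_matrix_block(fp, fp)
  neighbor <- (1 - sim) <= threshold
  diag(neighbor) <- FALSE
  n_nbrs <- rowSums(neighbor)
  order_idx <- order(-n_nbrs, seq_len(n))
  cluster <- rep(NA_integer_, n)
  centroid <- rep(FALSE, n)
  next_cluster <- 1L
  for (i in order_idx) {
    if (!is.na(cluster[i])) next
    cluster[i] <- next_cluster
    centroid[i] <- TRUE
    members <- which(neighbor[i, ] & is.na(cluster))
    cluster[members] <- next_cluster
    next_cluster <- next_cluster + 1L
  }
  tibble::tibble(molecule_id = mols$id, cluster_id = cluster,
                 is_centroid = centroid)
}
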