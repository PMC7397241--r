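# Bemis-Murcko scaffolds, graph frameworks, macrocycle detection, and
# scaffold diversity statistics.
#
# The Bemis-Murcko (BM) scaffold of a molecule is its ring systems plus
# the linkers connecting them, with side chains removed; atoms attached to
# the scaffold by a double or triple bond (exocyclic =O, =N, =S) are
# retained, which keeps e.g. the indolin-2-one carbonyl in the scaffold.
# The graph framework (cyclic skeleton) abstracts a BM scaffold by turning
# every atom into carbon and every bond into a single bond.

#' Bemis-Murcko scaffold
#'
#' @param smiles a single standardized SMILES string.
#' @return canonical SMILES of the scaffold; `""` for an acyclic molecule.
#' @export
bm_scaffold <- function(smiles) {
  mol <- parse_mol(smiles)
  core <- bm_core_atoms(mol)
  if (length(core) == 0) return("")
  sub <- mol_subgraph(mol, core)
  out <- mol_canonical_graph(sub$atoms, sub$bonds)
  if (is.na(out)) "" else out
}

# Atom indices of the BM scaffold: ring atoms and linker atoms (found by
# iteratively pruning non-ring atoms of heavy degree <= 1), plus any atom
# joined to that core by a bond of order >= 2.
bm_core_atoms <- function(mol) {
  if (!any(mol$atoms$ring)) return(integer())
  keep <- rep(TRUE, nrow(mol$atoms))
  repeat {
    deg <- tabulate(c(mol$bonds$a1[keep[mol$bonds$a1] & keep[mol$bonds$a2]],
                      mol$bonds$a2[keep[mol$bonds$a1] & keep[mol$bonds$a2]]),
                    nbins = nrow(mol$atoms))
    prune <- keep & !mol$atoms$ring & deg <= 1
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  core <- which(keep)
  meta <- mol$bonds[mol$bonds$order >= 2, , drop = FALSE]
  appendage <- c(meta$a2[meta$a1 %in% core], meta$a1[meta$a2 %in% core])
  sort(unique(c(core, appendage)))
}

#' Graph framework (cyclic skeleton)
#'
#' Abstracts a Bemis-Murcko scaffold: every atom becomes an uncharged
#' carbon and every bond a single bond, discarding aromaticity.
#'
#' @param bm canonical scaffold SMILES (possibly `""`).
#' @return canonical SMILES of the framework; `""` for an empty scaffold.
#' @export
graph_framework <- function(bm) {
  if (is.na(bm) || !nzchar(bm)) return("")
  mol <- parse_mol(bm)
  atoms <- dplyr::mutate(mol$atoms, element = "C", charge = 0L, isotope = 0L)
  bonds <- dplyr::mutate(mol$bonds, order = 1L)
  out <- mol_canonical_graph(atoms, bonds)
  if (is.na(out)) "" else out
}

#' Macrocycle detection
#'
#' A molecule is macrocyclic when its smallest set of smallest rings
#' contains a ring of more than `min_ring` atoms (strict inequality); a
#' fused envelope that is not itself a smallest ring does not count.
#'
#' @param smiles a single standardized SMILES string.
#' @param min_ring ring size that must be exceeded (default 12).
#' @return logical.
#' @export
detect_macrocycle <- function(smiles, min_ring = 12) {
  mol <- parse_mol(smiles)
  any(lengths(mol$sssr) > min_ring)
}

#' Scaffold decomposition of a molecule set
#'
#' @param mols molecule tibble with `smiles_std` (or a character vector).
#' @return tibble with `molecule_id`, `bm_smiles`, `gf_smiles`,
#'   `is_macrocyclic`.
#' @export
scaffold_table <- function(mols) {
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  stopifnot(all(c("id", "smiles_std") %in% names(mols)))
  bm <- vapply(mols$smiles_std, bm_scaffold, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    molecule_id = mols$id,
    bm_smiles = bm,
    gf_smiles = vapply(bm, graph_framework, character(1), USE.NAMES = FALSE),
    is_macrocyclic = vapply(mols$smiles_std, detect_macrocycle, logical(1),
                            USE.NAMES = FALSE)
  )
}

#' Scaffold diversity statistics
#'
#' Counts of unique Bemis-Murcko scaffolds and graph frameworks,
#' macrocycles, and the pairwise MACCS/Tanimoto similarity mean and
#' standard deviation of the molecule set.
#'
#' @param mols molecule tibble with `id` and `smiles_std`.
#' @param similarity compute pairwise fingerprint similarity statistics
#'   (skipped for singleton sets, reported as `NA`).
#' @return one-row tibble mirroring the scaffold diversity table of a
#'   dataset comparison: molecule, macrocycle, unique-scaffold counts with
#'   percentages, and similarity mean/SD.
#' @export
diversity_stats <- function(mols, similarity = TRUE) {
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  if (nrow(mols) == 0) stop("empty molecule set", call. = FALSE)
  sc <- scaffold_table(mols)
  n <- nrow(mols)
  uniq_bm <- unique(sc$bm_smiles[nzchar(sc$bm_smiles)])
  uniq_gf <- unique(sc$gf_smiles[nzchar(sc$gf_smiles)])
  sim <- if (similarity && n >= 2) {
    pairwise_similarity(mols, fingerprint = "maccs")
  } else {
    tibble::tibble(mean = NA_real_, sd = NA_real_)
  }
  tibble::tibble(
    n_molecules = n,
    n_macrocycles = sum(sc$is_macrocyclic),
    pct_macrocycles = 100 * sum(sc$is_macrocyclic) / n,
    n_unique_bm = length(uniq_bm),
    pct_unique_bm = 100 * length(uniq_bm) / n,
    n_unique_gf = length(uniq_gf),
    pct_unique_gf = 100 * length(uniq_gf) / n,
    similarity_mean = sim$mean,
    similarity_sd = sim$sd
  )
}

#' Match query scaffolds against a molecule library
#'
#' A library molecule is a hit for a query scaffold when its own scaffold,
#' at the requested abstraction level, equals the query. Both sides are
#' re-canonicalized before comparison.
#'
#' @param query_scaffolds character vector of scaffold SMILES.
#' @param library molecule tibble with `id` and `smiles_std`, or a
#'   precomputed [scaffold_table()].
#' @param level `"bm"` or `"gf"`.
#' @return list with `per_query` (tibble: `query`, `n_hits`) and
#'   `n_matched` (number of distinct library molecules hit by any query).
#' @export
scaffold_match <- function(query_scaffolds, library, level = c("bm", "gf")) {
  level <- match.arg(level)
  sc <- if (all(c("bm_smiles", "gf_smiles") %in% names(library))) {
    library
  } else {
    scaffold_table(library)
  }
  lib_key <- if (level == "bm") sc$bm_smiles else sc$gf_smiles
  q_can <- vapply(query_scaffolds, function(q) {
    if (!nzchar(q)) return("")
    q2 <- if (level == "gf") graph_framework(q) else ob_canonical(q)
    if (is.na(q2)) "" else q2
  }, character(1), USE.NAMES = FALSE)
  per_query <- tibble::tibble(
    query = query_scaffolds,
    n_hits = vapply(q_can, function(q) {
      if (!nzchar(q)) 0L else sum(lib_key == q)
    }, integer(1), USE.NAMES = FALSE)
  )
  matched <- unique(sc$molecule_id[lib_key %in% q_can[nzchar(q_can)]])
  list(per_query = per_query, n_matched = length(matched))
}
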