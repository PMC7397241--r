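# Conformer generation and principal-moments-of-inertia (PMI) shape
# analysis.
#
# 3D conformers are embedded with the ETKDG distance-geometry method and
# minimized with the MMFF94 force field (via RDKit, driven as a
# subprocess); the lowest-energy conformer of n_confs seeded embeddings
# represents each molecule. The inertia tensor is mass-weighted about the
# center of mass (explicit hydrogens included); the sorted principal
# moments I1 <= I2 <= I3 give the normalized ratios NPR1 = I1/I3 and
# NPR2 = I2/I3, placing each molecule in the rod-disc-sphere triangle
# whose vertices are represented by diacetylene (rod, 0/1), benzene
# (disc, 0.5/0.5) and adamantane (sphere, 1/1).

pmi_reference_molecules <- function() {
  tibble::tibble(
    id = c("REF_ROD", "REF_DISC", "REF_SPHERE"),
    name = c("diacetylene", "benzene", "adamantane"),
    smiles_std = c("C#CC#C", "c1ccccc1", "C1C2CC3CC1CC(C2)C3"),
    dataset_label = "REFERENCE"
  )
}

python_executable <- function() {
  exe <- getOption("kinasespace.python", Sys.which("python"))
  if (!nzchar(exe)) {
    stop("a 'python' interpreter with RDKit is required for conformer ",
         "embedding but was not found on PATH", call. = FALSE)
  }
  unname(exe)
}

embed_script <- function() pkg_file("python", "embed_confs.py")

#' Embed seeded conformers
#'
#' Generates `n_confs` ETKDG embeddings per molecule with a fixed random
#' seed, minimizes each with MMFF94, and keeps the lowest-energy
#' conformer. Deterministic for a given (structure, n_confs, seed).
#' Molecules that fail to embed are reported with a reason and excluded
#' from downstream PMI tables.
#'
#' @param mols molecule tibble with `id` and `smiles_std` (or a character
#'   vector of SMILES).
#' @param n_confs number of embeddings per molecule.
#' @param seed integer random seed.
#' @return tibble with `id`, `status`, `energy` (kcal/mol) and a `coords`
#'   list column of per-atom tibbles (`element`, `x`, `y`, `z`, `mass`).
#' @export
embed_conformers <- function(mols, n_confs = 10, seed = 42) {
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  stopifnot(all(c("id", "smiles_std") %in% names(mols)), n_confs >= 1)
  if (nrow(mols) == 0) {
    return(tibble::tibble(id = character(), status = character(),
                          energy = numeric(), coords = list()))
  }
  smi <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)), add = TRUE)
  writeLines(paste(mols$smiles_std, mols$id), smi)
  status_lines <- suppressWarnings(system2(
    python_executable(),
    c(embed_script(), smi, "--nconfs", n_confs, "--seed", seed,
      "--out", sdf),
    stdout = TRUE, stderr = FALSE
  ))
  code <- attr(status_lines, "status")
  if (!is.null(code) && code != 0) {
    stop("conformer embedding subprocess failed (exit ", code, ")",
         call. = FALSE)
  }
  st <- strsplit(status_lines, "\t")
  status <- tibble::tibble(
    id = vapply(st, `[`, "", 1),
    status = vapply(st, `[`, "", 2),
    detail = vapply(st, `[`, "", 3)
  )
  coords_by_id <- read_conformer_sdf(sdf)
  out <- dplyr::left_join(mols["id"], status, by = "id")
  out$energy <- suppressWarnings(
    ifelse(out$status == "ok", as.numeric(out$detail), NA_real_))
  out$coords <- coords_by_id[out$id]
  out$detail <- ifelse(out$status == "ok", NA_character_, out$detail)
  out
}

read_conformer_sdf <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    return(stats::setNames(list(), character()))
  }
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ids <- ChemmineR::sdfid(sdfset)
  res <- lapply(seq_along(sdfset), function(i) {
    ab <- ChemmineR::atomblock(sdfset[[i]])
    element <- sub("_.*$", "", rownames(ab))
    tibble::tibble(
      element = element,
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      mass = unname(atomic_weights[element])
    )
  })
  stats::setNames(res, ids)
}

#' Principal moments of inertia of one conformer
#'
#' Builds the mass-weighted inertia tensor about the center of mass,
#' diagonalizes it, and returns the sorted principal moments with their
#' normalized ratios.
#'
#' @param coords matrix-like with columns `x`, `y`, `z` (Angstrom).
#' @param masses atomic masses (amu), one per row of `coords`.
#' @return one-row tibble with `I1`, `I2`, `I3` (amu A^2), `NPR1`, `NPR2`.
#' @export
pmi_point <- function(coords, masses) {
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  stopifnot(nrow(xyz) >= 2, length(masses) == nrow(xyz))
  com <- colSums(xyz * masses) / sum(masses)
  r <- sweep(xyz, 2, com)
  if (max(abs(r)) < 1e-6) stop("degenerate geometry: all atoms coincident",
                               call. = FALSE)
  r2 <- rowSums(r^2)
  # I = sum_i m_i (|r_i|^2 delta_ab - r_ia r_ib)
  tensor <- matrix(0, 3, 3)
  for (a in 1:3) {
    for (b in 1:3) {
      tensor[a, b] <- sum(masses * ((a == b) * r2 - r[, a] * r[, b]))
    }
  }
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0] <- 0
  tibble::tibble(
    I1 = ev[1], I2 = ev[2], I3 = ev[3],
    NPR1 = ev[1] / ev[3], NPR2 = ev[2] / ev[3]
  )
}

#' PMI table of a molecule set
#'
#' Embeds every molecule ([embed_conformers()]), computes its PMI point,
#' and appends the three reference molecules that mark the triangle
#' vertices (diacetylene, benzene, adamantane). Per-molecule embedding
#' failures are dropped from the table, never fatal for the batch.
#'
#' @inheritParams embed_conformers
#' @param include_references append the rod/disc/sphere vertex molecules.
#' @return tibble with `id`, `dataset_label`, `I1`, `I2`, `I3`, `NPR1`,
#'   `NPR2`, `energy`.
#' @export
pmi_table <- function(mols, n_confs = 10, seed = 42,
                      include_references = TRUE) {
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  if (!"dataset_label" %in% names(mols)) mols$dataset_label <- "OTHER"
  sets <- mols[, c("id", "smiles_std", "dataset_label")]
  if (include_references) {
    sets <- dplyr::bind_rows(
      sets, pmi_reference_molecules()[, c("id", "smiles_std", "dataset_label")])
  }
  emb <- embed_conformers(sets, n_confs = n_confs, seed = seed)
  ok <- emb[!is.na(emb$status) & emb$status == "ok" &
              !vapply(emb$coords, is.null, logical(1)), ]
  pts <- purrr::map_dfr(ok$coords, function(cc) pmi_point(cc, cc$mass))
  dplyr::bind_cols(
    dplyr::left_join(ok[, c("id", "energy")],
                     sets[, c("id", "dataset_label")], by = "id"),
    pts
  )[, c("id", "dataset_label", "I1", "I2", "I3", "NPR1", "NPR2", "energy")]
}
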