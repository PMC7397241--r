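# Fused ring-system ensembles and their unpositioned / positioned
# encodings.
#
# Ring atoms are grouped into systems by fusion: rings sharing at least
# one atom (ortho-fused, bridged or spiro) belong to one system; rings
# joined only by an acyclic bond are separate systems. The unpositioned
# encoding replaces every substituent - including exocyclic double-bonded
# atoms - by hydrogen and re-perceives aromaticity, so an indolin-2-one
# ring system becomes the non-aromatic indoline. The positioned encoding
# keeps typed attachment points as dummy atoms labelled by first-shell
# class, and retains atoms double-bonded to the system unchanged:
#   [1*] attached atom is acyclic, non-aromatic, not halogen
#   [2*] attached atom is in a non-aromatic ring
#   [3*] attached atom is aromatic
#   [4*] attached atom is a halogen
# (precedence: double-bond retention, then halogen > aromatic > ring > 1).

#' Extract fused ring systems of one molecule
#'
#' @param smiles a single standardized SMILES string.
#' @return list of integer vectors, each the atom indices of one ring
#'   system (empty list for an acyclic molecule).
#' @export
extract_ring_systems <- function(smiles) {
  mol <- parse_mol(smiles)
  ring_atoms <- which(mol$atoms$ring)
  if (length(ring_atoms) == 0) return(list())
  rb <- mol$bonds[mol$bonds$ring, , drop = FALSE]
  # union-find over ring atoms via ring bonds; roots stored by atom idx
  comp <- stats::setNames(ring_atoms, ring_atoms)
  root <- function(i) {
    k <- as.character(i)
    while (comp[[k]] != i) {
      i <- comp[[k]]
      k <- as.character(i)
    }
    i
  }
  for (b in seq_len(nrow(rb))) {
    r1 <- root(rb$a1[b]); r2 <- root(rb$a2[b])
    if (r1 != r2) comp[[as.character(r2)]] <- r1
  }
  roots <- vapply(ring_atoms, root, numeric(1))
  unname(split(ring_atoms, roots))
}

system_ring_count <- function(mol, sys_atoms) {
  sum(vapply(mol$sssr, function(r) all(r %in% sys_atoms), logical(1)))
}

#' Unpositioned encoding of a ring system
#'
#' @param smiles molecule SMILES.
#' @param sys_atoms atom indices of one ring system (as returned by
#'   [extract_ring_systems()]).
#' @return canonical SMILES of the bare ring system, `NA` if the stripped
#'   system does not survive valence perception.
#' @export
encode_unpositioned <- function(smiles, sys_atoms) {
  mol <- parse_mol(smiles)
  sub <- mol_subgraph(mol, sys_atoms)
  mol_canonical_graph(sub$atoms, sub$bonds)
}

#' Positioned encoding of a ring system
#'
#' @inheritParams encode_unpositioned
#' @return canonical SMILES with isotope-labelled dummy attachment points
#'   (`[1*]`-`[4*]`) and retained exocyclic double-bonded atoms.
#' @export
encode_positioned <- function(smiles, sys_atoms) {
  mol <- parse_mol(smiles)
  atoms <- dplyr::filter(mol$atoms, .data$idx %in% sys_atoms)
  bonds <- dplyr::filter(mol$bonds, .data$a1 %in% sys_atoms &
                           .data$a2 %in% sys_atoms)
  boundary <- dplyr::filter(mol$bonds, xor(.data$a1 %in% sys_atoms,
                                           .data$a2 %in% sys_atoms))
  next_idx <- max(mol$atoms$idx) + 1L
  retained <- integer()
  for (b in seq_len(nrow(boundary))) {
    inside <- if (boundary$a1[b] %in% sys_atoms) boundary$a1[b] else boundary$a2[b]
    outside <- if (boundary$a1[b] %in% sys_atoms) boundary$a2[b] else boundary$a1[b]
    if (boundary$order[b] >= 2) {
      # double-bonded first shell is retained unchanged
      if (!outside %in% retained) {
        atoms <- dplyr::bind_rows(atoms, mol$atoms[outside, ])
        retained <- c(retained, outside)
      }
      bonds <- dplyr::bind_rows(bonds, tibble::tibble(
        a1 = inside, a2 = outside, order = boundary$order[b], ring = FALSE))
    } else {
      cls <- attachment_class(mol, outside)
      atoms <- dplyr::bind_rows(atoms, tibble::tibble(
        idx = next_idx, element = "*", charge = 0L, isotope = cls,
        nh = 0L, aromatic = FALSE, ring = FALSE))
      bonds <- dplyr::bind_rows(bonds, tibble::tibble(
        a1 = inside, a2 = next_idx, order = 1L, ring = FALSE))
      next_idx <- next_idx + 1L
    }
  }
  mol_canonical_graph(atoms, bonds)
}

# First-shell attachment class with fixed precedence so the four classes
# partition all single-bonded substituent atoms.
attachment_class <- function(mol, idx) {
  at <- mol$atoms[idx, ]
  if (at$element %in% halogen_elements) return(4L)
  if (at$aromatic) return(3L)
  if (at$ring) return(2L)
  1L
}

#' Ring-system table of a molecule set
#'
#' Extracts every fused ring system of every molecule and encodes it in
#' both forms. Systems whose stripped form cannot be re-perceived are
#' dropped with a warning.
#'
#' @param mols molecule tibble with `id` and `smiles_std` (or a character
#'   vector of SMILES).
#' @return tibble with `molecule_id`, `system_index`, `unpositioned`,
#'   `positioned`, `n_rings`, `is_bicycle`.
#' @export
ring_system_table <- function(mols) {
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  stopifnot(all(c("id", "smiles_std") %in% names(mols)))
  out <- purrr::map2_dfr(mols$id, mols$smiles_std, function(mid, smi) {
    systems <- extract_ring_systems(smi)
    if (length(systems) == 0) return(NULL)
    mol <- parse_mol(smi)
    purrr::imap_dfr(systems, function(sys, i) {
      nr <- system_ring_count(mol, sys)
      tibble::tibble(
        molecule_id = mid,
        system_index = as.integer(i),
        unpositioned = encode_unpositioned(smi, sys),
        positioned = encode_positioned(smi, sys),
        n_rings = nr,
        is_bicycle = nr == 2L
      )
    })
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(molecule_id = character(), system_index = integer(),
                          unpositioned = character(), positioned = character(),
                          n_rings = integer(), is_bicycle = logical()))
  }
  bad <- is.na(out$unpositioned) | is.na(out$positioned)
  if (any(bad)) {
    warning(sum(bad), " ring system(s) failed valence re-perception and ",
            "were dropped", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Frequency table of ring-system encodings
#'
#' Counts canonical ring-system strings over all occurrences (a molecule
#' contributes one count per occurrence). Rows are ordered by count
#' (decreasing) then key (lexicographic); singleton, unique and total
#' counts are attached as attribute `"summary"`.
#'
#' @param systems output of [ring_system_table()].
#' @param mode `"unpositioned"` or `"positioned"`.
#' @param bicycles_only restrict to two-ring systems (the default, the
#'   convention of the bicycle analysis).
#' @return tibble with `key`, `count`, `frequency`; retrieve totals with
#'   [frequency_summary()].
#' @export
bicycle_frequency <- function(systems, mode = c("unpositioned", "positioned"),
                              bicycles_only = TRUE) {
  mode <- match.arg(mode)
  sel <- if (bicycles_only) systems[systems$is_bicycle, , drop = FALSE] else systems
  keys <- sel[[mode]]
  if (length(keys) == 0) {
    out <- tibble::tibble(key = character(), count = integer(),
                          frequency = numeric())
    attr(out, "summary") <- tibble::tibble(n_total = 0L, n_unique = 0L,
                                           n_singletons = 0L)
    return(out)
  }
  tab <- table(keys)
  out <- tibble::tibble(key = names(tab), count = as.integer(tab))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$key)
  out$frequency <- out$count / sum(out$count)
  attr(out, "summary") <- tibble::tibble(
    n_total = sum(out$count),
    n_unique = nrow(out),
    n_singletons = sum(out$count == 1L)
  )
  out
}

#' Totals of a frequency table
#'
#' @param freq output of [bicycle_frequency()].
#' @return one-row tibble with `n_total`, `n_unique`, `n_singletons`.
#' @export
frequency_summary <- function(freq) {
  s <- attr(freq, "summary", exact = TRUE)
  if (is.null(s)) stop("no frequency summary attached", call. = FALSE)
  s
}

#' Fraction of molecules containing at least one bicycle
#'
#' @param mols molecule tibble with `id` and `smiles_std`.
#' @param systems optional precomputed [ring_system_table()].
#' @return a fraction in `[0, 1]`.
#' @export
bicycle_prevalence <- function(mols, systems = NULL) {
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  if (nrow(mols) == 0) stop("empty molecule set", call. = FALSE)
  if (is.null(systems)) systems <- ring_system_table(mols)
  with_bicycle <- unique(systems$molecule_id[systems$is_bicycle])
  length(intersect(mols$id, with_bicycle)) / nrow(mols)
}

# Strip dummies and retained exocyclic atoms from a positioned encoding:
# keeping only the ring atoms of the re-parsed string and re-perceiving
# must reproduce the unpositioned encoding.
strip_positioned <- function(positioned) {
  mol <- parse_mol(positioned)
  keep <- which(mol$atoms$ring)
  if (length(keep) == 0) return(NA_character_)
  sub <- mol_subgraph(mol, keep)
  mol_canonical_graph(sub$atoms, sub$bonds)
}
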