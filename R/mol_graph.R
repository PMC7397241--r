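# Molecular graphs as tidy tables.
#
# A molecule is represented as a pair of tibbles: `atoms` (element, formal
# charge, isotope label, implicit hydrogen count, aromaticity, ring
# membership) and `bonds` (Kekule bond orders, ring membership), plus the
# smallest set of smallest rings (SSSR). Structure perception (Kekule
# orders, implicit hydrogens, aromaticity) comes from OpenBabel; ring
# perception from ChemmineR. Scaffold and ring-system operations edit these
# tables and send the result back through OpenBabel for canonicalization,
# so aromaticity is always re-perceived on the edited structure.

the <- new.env(parent = emptyenv())
the$mol_cache <- new.env(parent = emptyenv())

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @param cache reuse a previously parsed graph for the same string.
#' @return an object of class `kin_mol`: a list with tibbles `atoms`
#'   (`idx`, `element`, `charge`, `isotope`, `nh`, `aromatic`, `ring`) and
#'   `bonds` (`a1`, `a2`, `order`, `ring`), the ring list `sssr`, and the
#'   logical `sssr_aromatic`.
#' @export
parse_mol <- function(smiles, cache = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (cache && !is.null(got <- the$mol_cache[[smiles]])) return(got)

  cml <- tryCatch(
    suppressWarnings(ob_convert(paste0(smiles, "\n"), "SMI", "CML")),
    error = function(e) NULL
  )
  if (is.null(cml) || !nzchar(cml)) {
    stop("unparseable SMILES: ", smiles, call. = FALSE)
  }
  doc <- xml2::read_xml(cml)
  atom_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='atom']")
  ids <- xml2::xml_attr(atom_nodes, "id")
  atoms <- tibble::tibble(
    idx = seq_along(atom_nodes),
    element = xml2::xml_attr(atom_nodes, "elementType"),
    charge = int_attr(atom_nodes, "formalCharge"),
    isotope = int_attr(atom_nodes, "isotope"),
    nh = int_attr(atom_nodes, "hydrogenCount")
  )
  bond_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='bond']")
  if (length(bond_nodes) > 0) {
    refs <- matrix(unlist(strsplit(xml2::xml_attr(bond_nodes, "atomRefs2"),
                                   " ", fixed = TRUE)), ncol = 2, byrow = TRUE)
    bonds <- tibble::tibble(
      a1 = match(refs[, 1], ids),
      a2 = match(refs[, 2], ids),
      order = as.integer(xml2::xml_attr(bond_nodes, "order"))
    )
  } else {
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  }

  sssr <- mol_sssr(atoms, bonds)
  atoms$aromatic <- if (length(sssr) > 0) {
    mol2_aromatic_atoms(smiles, nrow(atoms))
  } else {
    rep(FALSE, nrow(atoms))
  }
  ring_atoms <- unique(unlist(sssr))
  atoms$ring <- atoms$idx %in% ring_atoms
  ring_edges <- sssr_edge_keys(sssr)
  bonds$ring <- edge_key(bonds$a1, bonds$a2) %in% ring_edges
  sssr_aromatic <- vapply(sssr, function(r) all(atoms$aromatic[r]), logical(1))

  mol <- structure(
    list(atoms = atoms, bonds = bonds, sssr = sssr,
         sssr_aromatic = sssr_aromatic, smiles = smiles),
    class = "kin_mol"
  )
  if (cache) the$mol_cache[[smiles]] <- mol
  mol
}

int_attr <- function(nodes, attr) {
  v <- as.integer(xml2::xml_attr(nodes, attr))
  v[is.na(v)] <- 0L
  v
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

sssr_edge_keys <- function(sssr) {
  unique(unlist(lapply(sssr, function(r) {
    edge_key(r, c(r[-1], r[1]))
  })))
}

# Aromatic atom flags from OpenBabel's MOL2 writer (SYBYL atom types and
# 'ar' bond records). The CML and MOL2 conversions preserve atom order.
mol2_aromatic_atoms <- function(smiles, n_atoms) {
  mol2 <- suppressWarnings(ob_convert(paste0(smiles, "\n"), "SMI", "MOL2"))
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  sec <- function(name) {
    start <- match(paste0("@<TRIPOS>", name), lines)
    if (is.na(start)) return(character())
    rest <- lines[seq(start + 1L, length(lines))]
    stopline <- grep("^@<TRIPOS>", rest)
    if (length(stopline) > 0) rest <- rest[seq_len(stopline[1] - 1L)]
    rest[nzchar(trimws(rest))]
  }
  arom <- rep(FALSE, n_atoms)
  atom_lines <- sec("ATOM")
  if (length(atom_lines) > 0) {
    f <- strsplit(trimws(atom_lines), "\\s+")
    type <- vapply(f, `[`, "", 6)
    arom[seq_along(type)] <- grepl(".ar", type, fixed = TRUE)
  }
  bond_lines <- sec("BOND")
  if (length(bond_lines) > 0) {
    f <- strsplit(trimws(bond_lines), "\\s+")
    m <- t(vapply(f, `[`, character(4), 1:4))
    ar <- m[, 4] == "ar"
    arom[as.integer(m[ar, 2])] <- TRUE
    arom[as.integer(m[ar, 3])] <- TRUE
  }
  arom
}

# Smallest set of smallest rings as ordered atom-index cycles, computed on
# the bond graph: non-bridge edges span the ring subgraph; the smallest
# cycle through each ring edge is a candidate, and candidates are accepted
# shortest-first while linearly independent over GF(2) until the
# cyclomatic number of the ring subgraph is reached.
mol_sssr <- function(atoms, bonds) {
  if (nrow(bonds) < 3) return(list())
  n_v <- max(atoms$idx)
  g <- igraph::make_graph(as.vector(rbind(bonds$a1, bonds$a2)), n = n_v,
                          directed = FALSE)
  bridge_ids <- as.integer(igraph::bridges(g))
  ring_e <- setdiff(seq_len(nrow(bonds)), bridge_ids)
  if (length(ring_e) == 0) return(list())
  ring_v <- unique(c(bonds$a1[ring_e], bonds$a2[ring_e]))
  sub <- igraph::subgraph_from_edges(g, ring_e, delete.vertices = FALSE)
  memb <- igraph::components(sub)$membership
  k <- length(ring_e) - length(ring_v) + length(unique(memb[ring_v]))
  edge_index <- stats::setNames(seq_len(nrow(bonds)),
                                edge_key(bonds$a1, bonds$a2))
  # candidate cycles: smallest cycle through each ring edge
  cand <- lapply(ring_e, function(e) {
    g2 <- igraph::delete_edges(g, e)
    p <- suppressWarnings(
      igraph::shortest_paths(g2, from = bonds$a1[e], to = bonds$a2[e],
                             output = "vpath")$vpath[[1]]
    )
    as.integer(p)
  })
  cand <- cand[lengths(cand) >= 3]
  ord <- order(lengths(cand),
               vapply(cand, function(v) paste(sort(v), collapse = ","), ""))
  cand <- cand[ord]
  # greedy GF(2) independence over edge incidence vectors
  pivots <- list()
  chosen <- list()
  for (cyc in cand) {
    if (length(chosen) == k) break
    ei <- unname(edge_index[edge_key(cyc, c(cyc[-1], cyc[1]))])
    vec <- rep(FALSE, nrow(bonds))
    vec[ei] <- TRUE
    for (p in pivots) {
      if (vec[p$pivot]) vec <- xor(vec, p$vec)
    }
    piv <- which(vec)[1]
    if (!is.na(piv)) {
      pivots[[length(pivots) + 1L]] <- list(pivot = piv, vec = vec)
      chosen[[length(chosen) + 1L]] <- cyc
    }
  }
  chosen
}

# --- molblock writer ------------------------------------------------------

# Serialize atom/bond tables to a V2000 molblock (zero coordinates) so that
# OpenBabel can re-perceive and canonicalize an edited structure.
mol_write_molblock <- function(atoms, bonds, title = "") {
  n_at <- nrow(atoms)
  n_bd <- nrow(bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, atoms$element
  )
  bond_lines <- if (n_bd > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  } else character()
  prop_lines <- c(
    mol_prop_lines("CHG", atoms$idx[atoms$charge != 0],
                   atoms$charge[atoms$charge != 0]),
    mol_prop_lines("ISO", atoms$idx[atoms$isotope != 0],
                   atoms$isotope[atoms$isotope != 0])
  )
  paste(c(title, "  kinasespace", "", counts, atom_lines, bond_lines,
          prop_lines, "M  END", "$$$$"), collapse = "\n")
}

mol_prop_lines <- function(tag, idx, val) {
  if (length(idx) == 0) return(character())
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / 8))
  vapply(chunks, function(i) {
    paste0(sprintf("M  %s%3d", tag, length(i)),
           paste(sprintf("%4d%4d", idx[i], val[i]), collapse = ""))
  }, character(1))
}

# Canonical SMILES of an edited atom/bond table. Atoms are renumbered to be
# consecutive; implicit hydrogens and aromaticity are re-perceived by
# OpenBabel on read. Returns NA if the edited structure does not survive
# valence perception.
mol_canonical_graph <- function(atoms, bonds) {
  if (nrow(atoms) == 0) return("")
  map <- stats::setNames(seq_len(nrow(atoms)), atoms$idx)
  atoms <- dplyr::mutate(atoms, idx = as.integer(map[as.character(.data$idx)]))
  if (nrow(bonds) > 0) {
    bonds <- dplyr::mutate(
      bonds,
      a1 = as.integer(map[as.character(.data$a1)]),
      a2 = as.integer(map[as.character(.data$a2)])
    )
  }
  block <- mol_write_molblock(atoms, bonds)
  out <- tryCatch(
    suppressWarnings(ob_convert(block, "SDF", "CAN")),
    error = function(e) ""
  )
  out <- sub("\t.*$", "", trimws(out))
  if (!nzchar(out)) NA_character_ else out
}

# Keep a subset of atoms (by idx) and the bonds among them.
mol_subgraph <- function(mol, keep_idx) {
  list(
    atoms = dplyr::filter(mol$atoms, .data$idx %in% keep_idx),
    bonds = dplyr::filter(mol$bonds, .data$a1 %in% keep_idx &
                            .data$a2 %in% keep_idx)
  )
}

# Heavy-atom degree per atom.
mol_degrees <- function(mol) {
  tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = nrow(mol$atoms))
}

# Neighbor list: for each atom, a tibble of (nbr, order).
mol_neighbors <- function(mol, idx) {
  b <- mol$bonds
  sel <- b$a1 == idx | b$a2 == idx
  tibble::tibble(
    nbr = ifelse(b$a1[sel] == idx, b$a2[sel], b$a1[sel]),
    order = b$order[sel]
  )
}

# --- graph symmetry -------------------------------------------------------

# Atom symmetry classes by iterative neighborhood refinement (Morgan-style).
# Two atoms in different classes are guaranteed non-equivalent; atoms
# sharing a class are treated as equivalent.
mol_symmetry_classes <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- mol_degrees(mol)
  key <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$nh,
               mol$atoms$aromatic, mol$atoms$ring, deg)
  cls <- match(key, unique(key))
  ends <- c(mol$bonds$a1, mol$bonds$a2)
  other <- c(mol$bonds$a2, mol$bonds$a1)
  ords <- rep(mol$bonds$order, 2)
  nbr_idx <- split(other, factor(ends, levels = seq_len(n)))
  nbr_ord <- split(ords, factor(ends, levels = seq_len(n)))
  for (iter in seq_len(n + 1L)) {
    key <- vapply(seq_len(n), function(i) {
      nbk <- sort(paste0(nbr_ord[[i]], ":", cls[nbr_idx[[i]]]))
      paste(cls[i], paste(nbk, collapse = "|"))
    }, character(1))
    new_cls <- match(key, unique(key))
    if (length(unique(new_cls)) == length(unique(cls))) break
    cls <- new_cls
  }
  cls
}

# Potential tetrahedral stereocenters: sp3 carbons bearing at most one
# hydrogen whose substituents fall in pairwise distinct symmetry classes.
# Assigned and unassigned centers are both counted.
mol_stereocenters <- function(mol) {
  if (nrow(mol$atoms) == 0) return(integer())
  cls <- mol_symmetry_classes(mol)
  deg <- mol_degrees(mol)
  cand <- which(
    mol$atoms$element == "C" & !mol$atoms$aromatic &
      mol$atoms$nh <= 1 & (deg + mol$atoms$nh) == 4
  )
  keep <- vapply(cand, function(i) {
    nb <- mol_neighbors(mol, i)
    if (any(nb$order > 1)) return(FALSE)
    anyDuplicated(cls[nb$nbr]) == 0
  }, logical(1))
  cand[keep]
}

# --- element data ---------------------------------------------------------

# Standard atomic weights for the elements encountered in small-molecule
# drug discovery (IUPAC 2021 conventional values).
atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Se = 78.971, Br = 79.904,
  I = 126.904
)

halogen_elements <- c("F", "Cl", "Br", "I")
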