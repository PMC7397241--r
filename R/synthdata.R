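# Seeded synthetic-data generators with planted, known-answer structure.
#
# generate_library() decorates a pool of hand-annotated ring-system
# scaffolds with substituents at known positions and multiplicities, so
# that scaffold counts, bicycle frequency tables (both encodings),
# singleton counts, macrocycle counts, bicycle prevalence and the
# Lipinski violation distribution are all known by construction. The
# planted truth is assembled from the construction bookkeeping (atomic
# arithmetic for MW/HBA/HBD, hand-annotated ring metadata, an independent
# Wildman-Crippen implementation for ClogP flags) - never from the
# package's own analysis code paths.

# --- scaffold and substituent pools --------------------------------------

# Hand-annotated scaffold pool. `unpositioned` is the hand-derived bare
# ring-system form (note oxindole -> indoline: stripping the exocyclic
# carbonyl leaves a non-aromatic five-membered ring). `n_rings`,
# `is_bicycle` and `is_macrocyclic` are hand-derived from the structures.
default_scaffold_pool <- function() {
  tibble::tibble(
    name = c("quinazoline", "quinoline", "indole", "oxindole", "purine",
             "benzene", "cyclotridecane"),
    smiles = c("c1ccc2ncncc2c1", "c1ccc2ncccc2c1", "c1ccc2[nH]ccc2c1",
               "O=C1Cc2ccccc2N1", "c1ncc2[nH]cnc2n1",
               "c1ccccc1", "C1CCCCCCCCCCCC1"),
    unpositioned = c("c1ccc2ncncc2c1", "c1ccc2ncccc2c1", "c1ccc2[nH]ccc2c1",
                     "C1Cc2ccccc2N1", "c1ncc2[nH]cnc2n1",
                     "c1ccccc1", "C1CCCCCCCCCCCC1"),
    n_rings = c(2L, 2L, 2L, 2L, 2L, 1L, 1L),
    is_bicycle = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    is_macrocyclic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    multiplicity = c(30L, 20L, 10L, 4L, 1L, 30L, 5L)
  )
}

# Substituent pool. `class` is the hand-assigned positioned-encoding
# attachment class of the first shell atom (1 generic acyclic, 2
# non-aromatic ring, 3 aromatic, 4 halogen); `has_ring` marks substituents
# that join the Bemis-Murcko scaffold.
default_substituent_pool <- function() {
  tibble::tibble(
    name = c("methyl", "methoxy", "dimethylamino", "phenyl", "cyclohexyl",
             "fluoro", "chloro", "bromo"),
    smiles = c("C", "OC", "N(C)C", "c1ccccc1", "C1CCCCC1", "F", "Cl", "Br"),
    class = c(1L, 1L, 1L, 3L, 2L, 4L, 4L, 4L),
    has_ring = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Specification of a synthetic molecule library
#'
#' @param scaffold_pool tibble like [default_scaffold_pool()]: hand
#'   annotated scaffolds with multiplicities.
#' @param substituent_pool tibble like [default_substituent_pool()].
#' @param n_substituents_range integer range (min, max) of substituents
#'   per molecule.
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return a `kin_library_spec` list.
#' @export
library_spec <- function(scaffold_pool = default_scaffold_pool(),
                         substituent_pool = default_substituent_pool(),
                         n_substituents_range = c(1L, 3L),
                         seed = 1L) {
  stopifnot(
    all(scaffold_pool$multiplicity >= 1),
    length(n_substituents_range) == 2,
    n_substituents_range[1] >= 0,
    n_substituents_range[1] <= n_substituents_range[2]
  )
  structure(
    list(scaffold_pool = scaffold_pool,
         substituent_pool = substituent_pool,
         n_substituents_range = as.integer(n_substituents_range),
         seed = as.integer(seed)),
    class = "kin_library_spec"
  )
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Independent Wildman-Crippen logP used only for planting rule-of-five
# truth (RDKit implementation, separate from the descriptor path).
crippen_logp_oracle <- function(smiles) {
  script <- pkg_file("python", "crippen_logp.py")
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  ids <- sprintf("s%06d", seq_along(smiles))
  writeLines(paste(smiles, ids), smi)
  out <- suppressWarnings(system2(python_executable(), c(script, smi),
                                  stdout = TRUE, stderr = FALSE))
  f <- strsplit(out, "\t")
  vals <- stats::setNames(as.numeric(vapply(f, `[`, "", 2)),
                          vapply(f, `[`, "", 1))
  unname(vals[ids])
}

# Molecular weight by atomic arithmetic over a parsed graph (heavy atoms
# plus implicit hydrogens); generator-side bookkeeping.
graph_mw <- function(mol) {
  sum(atomic_weights[mol$atoms$element]) + sum(mol$atoms$nh) *
    atomic_weights[["H"]]
}

# --- library generation ---------------------------------------------------

#' Generate a synthetic molecule library with planted truth
#'
#' Each scaffold of the pool is emitted `multiplicity` times, decorated at
#' randomly chosen ring CH positions with randomly chosen substituents.
#' Ground truth for every downstream analysis is recorded from the
#' construction itself. Molecules whose Wildman-Crippen logP falls within
#' the guard band around the rule-of-five threshold (|logP - 5| <= 0.25)
#' or whose weight falls within 0.5 Da of 500 are re-decorated so that
#' rule flags are unambiguous; after bounded retries a molecule is
#' skipped and the truth adjusted.
#'
#' @param spec a [library_spec()].
#' @return list with `molecules` (standardized molecule tibble) and
#'   `truth`: `bm_counts`, `bicycle_unpositioned`, `bicycle_positioned`
#'   (key/count tibbles), `n_macrocycles`, `bicycle_prevalence`,
#'   `lipinski_distribution`, `n_molecules`.
#' @export
generate_library <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "kin_library_spec"))
  pool <- spec$scaffold_pool
  subs <- spec$substituent_pool
  scaffold_mols <- lapply(pool$smiles, parse_mol)
  sub_mols <- lapply(subs$smiles, parse_mol)
  # ring-CH attachment positions per scaffold
  positions <- lapply(scaffold_mols, function(m) {
    which(m$atoms$ring & m$atoms$element == "C" & m$atoms$nh >= 1)
  })
  sample_vec <- function(x, k) x[sample.int(length(x), k)]
  max_tries <- 20L
  # all candidate decorations are drawn up front so the sequence is a pure
  # function of the seed; graphs are only built for candidates actually
  # evaluated
  draws <- with_local_seed(spec$seed, {
    idx_scaffold <- rep(seq_len(nrow(pool)), pool$multiplicity)
    lapply(idx_scaffold, function(si) {
      list(si = si, tries = lapply(seq_len(max_tries), function(t) {
        rng <- spec$n_substituents_range
        k <- sample_vec(seq(rng[1], rng[2]), 1)
        k <- min(k, length(positions[[si]]))
        list(pos = sample_vec(positions[[si]], k),
             sub = if (k > 0) sample.int(nrow(subs), k, replace = TRUE)
                   else integer())
      }))
    })
  })
  n_mol <- length(draws)
  accepted <- vector("list", n_mol)
  try_idx <- rep(1L, n_mol)
  alive <- rep(TRUE, n_mol)
  while (any(alive & vapply(accepted, is.null, logical(1)))) {
    open <- which(alive & vapply(accepted, is.null, logical(1)))
    cand <- lapply(open, function(i) {
      d <- draws[[i]]
      build_decoration(d$si, d$tries[[try_idx[i]]], pool, subs,
                       scaffold_mols, sub_mols, with_keys = FALSE)
    })
    lp <- crippen_logp_oracle(vapply(cand, `[[`, "", "smiles"))
    for (j in seq_along(open)) {
      i <- open[j]
      ok <- !is.na(cand[[j]]$smiles) && !is.na(lp[j]) &&
        abs(lp[j] - 5) > 0.25 && abs(cand[[j]]$mw - 500) > 0.5
      if (ok) {
        rec <- cand[[j]]
        rec$logp <- lp[j]
        rec$si <- draws[[i]]$si
        accepted[[i]] <- rec
      } else {
        try_idx[i] <- try_idx[i] + 1L
        if (try_idx[i] > max_tries) alive[i] <- FALSE
      }
    }
  }
  skipped <- sum(!alive)
  if (skipped > 0) {
    message("skipped ", skipped,
            " molecule(s): no guard-band-safe decoration found")
  }
  records <- purrr::compact(accepted)
  # truth keys (Bemis-Murcko reference and positioned bicycle form) are
  # built from the accepted construction only
  records <- lapply(records, function(r) {
    keys <- build_decoration(r$si, r, pool, subs, scaffold_mols, sub_mols,
                             with_keys = TRUE)
    r$bm_key <- keys$bm_key
    r$positioned_key <- keys$positioned_key
    r
  })
  molecules <- tibble::tibble(
    id = sprintf("S%05d", seq_along(records)),
    name = vapply(records, function(r) pool$name[r$si], ""),
    smiles_input = vapply(records, `[[`, "", "smiles"),
    dataset_label = "OTHER",
    phase = NA_integer_
  )
  molecules$smiles_std <- molecules$smiles_input
  molecules$inchikey <- ob_inchikey(molecules$smiles_std)
  truth <- assemble_truth(records, pool)
  list(molecules = molecules, truth = truth)
}

# Assemble one decorated molecule from its construction recipe. With
# `with_keys = FALSE` returns the decorated SMILES plus arithmetic
# MW/HBA/HBD; with `with_keys = TRUE` returns the Bemis-Murcko reference
# key (scaffold plus ring-bearing substituents) and the positioned
# bicycle key (scaffold plus class-labelled dummies).
build_decoration <- function(si, tr, pool, subs, scaffold_mols, sub_mols,
                             with_keys = FALSE) {
  smol <- scaffold_mols[[si]]
  atoms <- smol$atoms
  bonds <- smol$bonds
  bm_atoms <- smol$atoms
  bm_bonds <- smol$bonds
  pos_atoms <- smol$atoms
  pos_bonds <- smol$bonds
  offset <- max(atoms$idx)
  pos_offset <- offset
  hba <- sum(smol$atoms$element %in% c("N", "O"))
  hbd <- sum(smol$atoms$nh[smol$atoms$element %in% c("N", "O")])
  mw <- graph_mw(smol)
  for (j in seq_along(tr$sub)) {
    fm <- sub_mols[[tr$sub[j]]]
    if (!with_keys) {
      frag_atoms <- dplyr::mutate(fm$atoms, idx = .data$idx + offset)
      frag_bonds <- dplyr::mutate(fm$bonds, a1 = .data$a1 + offset,
                                  a2 = .data$a2 + offset)
      atoms <- dplyr::bind_rows(atoms, frag_atoms)
      bonds <- dplyr::bind_rows(
        bonds, frag_bonds,
        tibble::tibble(a1 = tr$pos[j], a2 = offset + 1L, order = 1L,
                       ring = FALSE))
      offset <- max(atoms$idx)
      mw <- mw + graph_mw(fm) - atomic_weights[["H"]]
      hba <- hba + sum(fm$atoms$element %in% c("N", "O"))
      hbd <- hbd + sum(fm$atoms$nh[fm$atoms$element %in% c("N", "O")])
      # the new bond consumes one implicit H of the fragment head atom
      if (fm$atoms$element[1] %in% c("N", "O") && fm$atoms$nh[1] > 0) {
        hbd <- hbd - 1L
      }
    } else {
      if (subs$has_ring[tr$sub[j]]) {
        bm_off <- max(bm_atoms$idx)
        bm_atoms <- dplyr::bind_rows(
          bm_atoms, dplyr::mutate(fm$atoms, idx = .data$idx + bm_off))
        bm_bonds <- dplyr::bind_rows(
          bm_bonds,
          dplyr::mutate(fm$bonds, a1 = .data$a1 + bm_off,
                        a2 = .data$a2 + bm_off),
          tibble::tibble(a1 = tr$pos[j], a2 = bm_off + 1L, order = 1L,
                         ring = FALSE))
      }
      pos_atoms <- dplyr::bind_rows(pos_atoms, tibble::tibble(
        idx = pos_offset + 1L, element = "*", charge = 0L,
        isotope = subs$class[tr$sub[j]], nh = 0L, aromatic = FALSE,
        ring = FALSE))
      pos_bonds <- dplyr::bind_rows(pos_bonds, tibble::tibble(
        a1 = tr$pos[j], a2 = pos_offset + 1L, order = 1L, ring = FALSE))
      pos_offset <- pos_offset + 1L
    }
  }
  if (!with_keys) {
    list(smiles = mol_canonical_graph(atoms, bonds),
         mw = mw, hba = hba, hbd = hbd, pos = tr$pos, sub = tr$sub)
  } else {
    list(bm_key = mol_canonical_graph(bm_atoms, bm_bonds),
         positioned_key = if (pool$is_bicycle[si]) {
           mol_canonical_graph(pos_atoms, pos_bonds)
         } else NA_character_)
  }
}

assemble_truth <- function(records, pool) {
  si <- vapply(records, `[[`, 0L, "si")
  count_tbl <- function(keys) {
    if (length(keys) == 0) {
      return(tibble::tibble(key = character(), count = integer()))
    }
    tab <- table(keys)
    out <- tibble::tibble(key = names(tab), count = as.integer(tab))
    dplyr::arrange(out, dplyr::desc(.data$count), .data$key)
  }
  unpos_keys <- vapply(pool$unpositioned, function(s) ob_canonical(s),
                       character(1))
  lip <- vapply(records, function(r) {
    (r$mw > 500) + (r$logp > 5) + (r$hba > 10) + (r$hbd > 5)
  }, numeric(1))
  lip_cls <- factor(ifelse(lip > 2, ">2", as.character(lip)),
                    levels = c("0", "1", "2", ">2"))
  list(
    n_molecules = length(records),
    bm_counts = count_tbl(vapply(records, `[[`, "", "bm_key")),
    bicycle_unpositioned = count_tbl(unpos_keys[si[pool$is_bicycle[si]]]),
    bicycle_positioned = count_tbl(
      vapply(records[pool$is_bicycle[si]], `[[`, "", "positioned_key")),
    n_macrocycles = sum(pool$is_macrocyclic[si]),
    bicycle_prevalence = mean(pool$is_bicycle[si]),
    lipinski_distribution = tibble::tibble(
      class = levels(lip_cls),
      n = as.integer(table(lip_cls))
    )
  )
}

# --- descriptor tables ----------------------------------------------------

#' Generate a multivariate-normal descriptor table
#'
#' @param n number of rows.
#' @param means,sds per-variable means and standard deviations (named
#'   vectors; names become column names).
#' @param correlation correlation matrix (positive semi-definite).
#' @param seed integer seed.
#' @return tibble with one column per variable.
#' @export
generate_descriptor_table <- function(n, means, sds,
                                      correlation = diag(length(means)),
                                      seed = 1L) {
  p <- length(means)
  stopifnot(length(sds) == p, nrow(correlation) == p, ncol(correlation) == p)
  if (min(eigen(correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  sigma <- diag(sds, p) %*% correlation %*% diag(sds, p)
  x <- with_local_seed(seed, MASS::mvrnorm(n, mu = means, Sigma = sigma))
  nm <- names(means)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  colnames(x) <- nm
  tibble::as_tibble(x)
}

#' Generate a descriptor table with planted rule-of-five violation counts
#'
#' Constructs MW/ClogP/HBA/HBD/TPSA/NRB columns such that exactly the
#' requested numbers of molecules fall in the Lipinski violation classes
#' 0, 1, 2 and >2 (values are placed far from the thresholds).
#'
#' @param counts named integer vector with names `"0"`, `"1"`, `"2"`,
#'   `">2"`.
#' @param seed integer seed (row order is shuffled).
#' @return descriptor tibble.
#' @export
plant_violation_table <- function(counts = c("0" = 5, "1" = 3, "2" = 2,
                                             ">2" = 1), seed = 1L) {
  stopifnot(identical(names(counts), c("0", "1", "2", ">2")))
  base <- tibble::tibble(MW = 350, ClogP = 2.5, HBA = 4, HBD = 1,
                         TPSA = 80, NRB = 5)
  row_for <- function(v) {
    r <- base
    if (v >= 1) r$MW <- 650
    if (v >= 2) r$ClogP <- 7.5
    if (v >= 3) r$HBA <- 14
    if (v >= 4) r$HBD <- 8
    r
  }
  rows <- purrr::map2_dfr(c(0, 1, 2, 3), counts, function(v, k) {
    dplyr::bind_rows(replicate(k, row_for(v), simplify = FALSE))
  })
  with_local_seed(seed, rows[sample(nrow(rows)), ])
}
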