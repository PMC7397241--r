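# The physicochemical descriptor panel, drug-likeness rule profiling, and
# mean +/- 2 SD guideline ranges.
#
# Conventions (documented in the methods vignette):
#  * HBA / HBD follow the N+O and NH+OH counting of the rule of five.
#  * ClogP is the Wildman-Crippen atom-contribution model; TPSA is Ertl's
#    topological polar surface area (both via OpenBabel).
#  * NCA counts potential tetrahedral stereocenters, assigned or not.
#  * MQN8 / MQN10 are components 8 and 10 (1-based) of the 42-component
#    Molecular Quantum Numbers vector: acyclic nitrogen and acyclic oxygen
#    atom counts.

descriptor_names <- c("MW", "ClogP", "TPSA", "HBA", "HBD", "NRB", "NHA",
                      "NAR", "NCA", "FCSP3", "MQN8", "MQN10")

count_descriptors <- c("HBA", "HBD", "NRB", "NHA", "NAR", "NCA",
                       "MQN8", "MQN10")

#' Names of the ten descriptors used for the PCA
#'
#' @return character vector of descriptor column names.
#' @export
pca_descriptor_names <- function() {
  c("MW", "ClogP", "TPSA", "HBA", "HBD", "NRB", "NAR", "FCSP3",
    "MQN8", "MQN10")
}

#' Compute the physicochemical descriptor panel
#'
#' Computes the twelve-descriptor panel for each molecule: molecular weight
#' (MW, Da), Wildman-Crippen ClogP, topological polar surface area (TPSA,
#' A^2), hydrogen bond acceptors (HBA, N+O) and donors (HBD, NH+OH),
#' rotatable bonds (NRB), heavy atoms (NHA), aromatic rings (NAR), chiral
#' atoms (NCA), fraction of sp3 carbons (FCSP3), and the acyclic nitrogen
#' (MQN8) and acyclic oxygen (MQN10) atom counts.
#'
#' @param mols molecule tibble with a `smiles_std` column (a character
#'   vector of standardized SMILES also works).
#' @return tibble with `id` (when present) and one column per descriptor.
#' @export
compute_descriptors <- function(mols) {
  if (is.character(mols)) {
    mols <- tibble::tibble(id = sprintf("M%05d", seq_along(mols)),
                           smiles_std = mols)
  }
  stopifnot("smiles_std" %in% names(mols))
  if (any(is.na(mols$smiles_std))) {
    stop("missing smiles_std: standardize molecules first", call. = FALSE)
  }
  graph_part <- purrr::map_dfr(mols$smiles_std, descriptor_graph_row)
  ob_part <- ob_lipophilicity_panel(mols$smiles_std)
  if (anyNA(ob_part)) {
    stop("descriptor computation failed for ", sum(!stats::complete.cases(ob_part)),
         " molecule(s)", call. = FALSE)
  }
  out <- dplyr::bind_cols(ob_part, graph_part)
  out <- out[, descriptor_names]
  if ("id" %in% names(mols)) {
    out <- dplyr::bind_cols(mols[, intersect(c("id", "dataset_label"),
                                             names(mols))], out)
  }
  tibble::as_tibble(out)
}

descriptor_graph_row <- function(smiles) {
  mol <- parse_mol(smiles)
  at <- mol$atoms
  deg <- mol_degrees(mol)
  in_triple <- rep(FALSE, nrow(at))
  trip <- mol$bonds[mol$bonds$order >= 3, , drop = FALSE]
  in_triple[c(trip$a1, trip$a2)] <- TRUE
  rotatable <- with(mol$bonds,
    order == 1 & !ring & deg[a1] >= 2 & deg[a2] >= 2 &
      !in_triple[a1] & !in_triple[a2])
  has_multiple <- rep(FALSE, nrow(at))
  mult <- mol$bonds[mol$bonds$order >= 2, , drop = FALSE]
  has_multiple[c(mult$a1, mult$a2)] <- TRUE
  is_c <- at$element == "C"
  sp3_c <- is_c & !at$aromatic & !has_multiple
  tibble::tibble(
    HBA = sum(at$element %in% c("N", "O")),
    HBD = sum(at$nh[at$element %in% c("N", "O")]),
    NRB = sum(rotatable),
    NHA = nrow(at),
    NAR = sum(mol$sssr_aromatic),
    NCA = length(mol_stereocenters(mol)),
    FCSP3 = if (any(is_c)) sum(sp3_c) / sum(is_c) else 0,
    MQN8 = sum(at$element == "N" & !at$ring),
    MQN10 = sum(at$element == "O" & !at$ring)
  )
}

#' Lipinski and Veber rule profiles
#'
#' Flags each molecule against the rule-of-five thresholds (MW > 500,
#' ClogP > 5, HBA > 10, HBD > 5) and the Veber thresholds (TPSA > 140,
#' NRB > 10). A violation requires a strict inequality, so a molecule at
#' exactly MW = 500 is compliant.
#'
#' @param descriptors output of [compute_descriptors()].
#' @return the input with logical flag columns (`viol_mw`, `viol_clogp`,
#'   `viol_hba`, `viol_hbd`, `viol_tpsa`, `viol_nrb`) and the totals
#'   `lipinski_violations` (0-4) and `veber_violations` (0-2).
#' @export
rule_profile <- function(descriptors) {
  d <- tibble::as_tibble(descriptors)
  stopifnot(all(c("MW", "ClogP", "HBA", "HBD", "TPSA", "NRB") %in% names(d)))
  d <- dplyr::mutate(
    d,
    viol_mw = .data$MW > 500,
    viol_clogp = .data$ClogP > 5,
    viol_hba = .data$HBA > 10,
    viol_hbd = .data$HBD > 5,
    viol_tpsa = .data$TPSA > 140,
    viol_nrb = .data$NRB > 10
  )
  dplyr::mutate(
    d,
    lipinski_violations = .data$viol_mw + .data$viol_clogp +
      .data$viol_hba + .data$viol_hbd,
    veber_violations = .data$viol_tpsa + .data$viol_nrb
  )
}

#' Distribution of rule-of-five violation counts
#'
#' Tabulates molecules into the violation classes `0`, `1`, `2` and `>2`.
#'
#' @param descriptors output of [compute_descriptors()] or [rule_profile()].
#' @param rule `"lipinski"` or `"veber"` (classes `0`, `1`, `2`, `>2`
#'   are reported for either; Veber counts can only populate 0-2).
#' @return tibble with columns `class`, `n`, `percent`.
#' @export
violation_distribution <- function(descriptors, rule = c("lipinski", "veber")) {
  rule <- match.arg(rule)
  d <- tibble::as_tibble(descriptors)
  if (nrow(d) == 0) stop("empty descriptor table", call. = FALSE)
  col <- paste0(rule, "_violations")
  if (!col %in% names(d)) d <- rule_profile(d)
  v <- d[[col]]
  cls <- factor(ifelse(v > 2, ">2", as.character(v)),
                levels = c("0", "1", "2", ">2"))
  tab <- table(cls)
  tibble::tibble(
    class = names(tab),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / length(v)
  )
}

#' Derive mean +/- k SD descriptor guidelines
#'
#' For each descriptor column, computes the sample mean, the sample
#' standard deviation (n - 1 denominator), and the guideline range
#' `mean +/- k_sd * sd`. For a normally distributed property and the
#' default `k_sd = 2`, the range covers 95.4% of molecules. Lower bounds
#' of count descriptors are clamped at zero; `lower_print` / `upper_print`
#' give the rounded presentation form (integers for count descriptors,
#' one decimal otherwise).
#'
#' @param descriptors descriptor tibble (only numeric descriptor columns
#'   are profiled).
#' @param k_sd width of the range in standard deviations.
#' @return tibble with columns `descriptor`, `mean`, `sd`, `lower`,
#'   `upper`, `lower_print`, `upper_print`.
#' @export
derive_guidelines <- function(descriptors, k_sd = 2) {
  d <- tibble::as_tibble(descriptors)
  vars <- intersect(descriptor_names, names(d))
  if (length(vars) == 0) {
    vars <- names(d)[vapply(d, is.numeric, logical(1))]
  }
  if (nrow(d) < 2) {
    stop("at least two molecules are required to derive guidelines",
         call. = FALSE)
  }
  purrr::map_dfr(vars, function(v) {
    x <- d[[v]]
    m <- mean(x)
    s <- stats::sd(x)
    lo <- m - k_sd * s
    up <- m + k_sd * s
    is_count <- v %in% count_descriptors
    if (is_count) lo <- max(0, lo)
    rnd <- function(b, f) if (is_count) f(b) else round(b, 1)
    tibble::tibble(
      descriptor = v, mean = m, sd = s, lower = lo, upper = up,
      lower_print = rnd(lo, floor), upper_print = rnd(up, ceiling)
    )
  })
}

#' Fraction of values inside a guideline range
#'
#' @param x numeric vector.
#' @param guideline one row of [derive_guidelines()] output.
#' @return fraction of `x` within `[lower, upper]`.
#' @export
guideline_coverage <- function(x, guideline) {
  mean(x >= guideline$lower & x <= guideline$upper)
}
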