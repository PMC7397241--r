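# Building a kinase-bioactivity comparison set from an activity table and
# assembling labelled molecule sets.

activity_types <- c("IC50", "Ki", "Kd")

#' Read a bioactivity table
#'
#' Expected columns: `smiles`, `target_id`, `target_is_kinase` (logical),
#' `activity_type` (IC50/Ki/Kd/other), `pchembl` (-log10 molar activity).
#'
#' @param path CSV file.
#' @return tibble of activity rows; malformed rows (missing SMILES or
#'   non-finite pchembl) are dropped with a message.
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("smiles", "target_id", "target_is_kinase", "activity_type",
            "pchembl")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("activity table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  bad <- is.na(df$smiles) | !nzchar(as.character(df$smiles)) |
    !is.finite(df$pchembl)
  if (any(bad)) {
    message("dropping ", sum(bad), " malformed activity row(s)")
    df <- df[!bad, , drop = FALSE]
  }
  df$target_is_kinase <- as.logical(df$target_is_kinase)
  df
}

#' Build a kinase-active molecule set from activity rows
#'
#' Keeps molecules with at least one activity row on a kinase target of
#' type IC50, Ki or Kd with pchembl strictly greater than `pchembl_min`
#' (> 6 corresponds to sub-micromolar potency), then standardizes,
#' deduplicates, and removes members of the exclusion set (e.g. molecules
#' already present in a curated clinical registry).
#'
#' @param rows activity tibble as from [read_activities()].
#' @param exclusion character vector of InChIKeys to drop.
#' @param pchembl_min potency threshold (strict inequality).
#' @return labelled molecule tibble (`dataset_label = "CHEMBL_PKI"`) with
#'   a standardization report attribute.
#' @export
build_pki_set <- function(rows, exclusion = character(), pchembl_min = 6) {
  rows <- tibble::as_tibble(rows)
  qual <- rows$target_is_kinase %in% TRUE &
    rows$activity_type %in% activity_types &
    rows$pchembl > pchembl_min
  smiles <- unique(rows$smiles[qual])
  mols <- tibble::tibble(
    id = sprintf("C%05d", seq_along(smiles)),
    name = "",
    smiles_input = smiles,
    dataset_label = "CHEMBL_PKI",
    phase = NA_integer_
  )
  mols <- deduplicate_molecules(standardize_molecules(mols))
  report <- standardization_report(mols)
  excluded <- mols$inchikey %in% exclusion
  out <- mols[!excluded, , drop = FALSE]
  attr(out, "report") <- report
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Merge labelled molecule sets
#'
#' Binds several labelled molecule tables and reports InChIKeys present
#' in more than one set. When one key carries conflicting labels, the
#' first set wins and a warning is raised; later duplicates of a key are
#' dropped from the merged table.
#'
#' @param ... molecule tibbles, each with a `dataset_label` column.
#' @return list with `molecules` (merged tibble) and `overlap` (tibble:
#'   `inchikey`, `labels`).
#' @export
assemble_comparison <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  all_rows <- dplyr::bind_rows(sets)
  by_key <- dplyr::summarise(
    dplyr::group_by(all_rows, .data$inchikey),
    labels = paste(unique(.data$dataset_label), collapse = "+"),
    n_sets = dplyr::n_distinct(.data$dataset_label),
    .groups = "drop"
  )
  overlap <- dplyr::filter(by_key, .data$n_sets > 1)[, c("inchikey", "labels")]
  if (nrow(overlap) > 0) {
    warning(nrow(overlap), " InChIKey(s) present in more than one set; ",
            "first set wins", call. = FALSE)
  }
  merged <- all_rows[!duplicated(all_rows$inchikey), , drop = FALSE]
  list(molecules = tibble::as_tibble(merged), overlap = overlap)
}
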