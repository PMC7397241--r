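# Reading, standardizing, deduplicating and writing molecule sets.
#
# A molecule table is an ordinary tibble with columns
#   id, name, smiles_input, smiles_std, inchikey, dataset_label, phase
# so that every pipeline stage composes with dplyr verbs. Standardization
# keeps the largest organic fragment, neutralizes formal charges where a
# neutral form exists, and canonicalizes; duplicate identity is the
# standard InChIKey, whose mobile-hydrogen layer also collapses common
# tautomers of one parent structure.

dataset_labels <- c("APPROVED_PKI", "CLINICAL_PKI", "CHEMBL_PKI", "OTHER")

#' Read a molecule set
#'
#' Reads molecules from a `.smi` file (one SMILES per line with an optional
#' whitespace-separated name), an SDF, or a delimited text file with a
#' SMILES column. Unparseable entries are kept in the returned table (they
#' are counted and dropped during [standardize_molecules()] /
#' [deduplicate_molecules()]); empty SMILES cells are kept as empty strings.
#'
#' @param path input file.
#' @param format `"smi"`, `"sdf"`, `"csv"`, or `"auto"` (by extension).
#' @param smiles_col,name_col,phase_col column names used for `csv` input.
#' @param label dataset label applied to all records (`APPROVED_PKI`,
#'   `CLINICAL_PKI`, `CHEMBL_PKI` or `OTHER`).
#' @return a tibble with columns `id`, `name`, `smiles_input`,
#'   `dataset_label`, `phase`, in input order.
#' @export
read_molecules <- function(path, format = c("auto", "smi", "sdf", "csv"),
                           smiles_col = "smiles", name_col = NULL,
                           phase_col = NULL, label = "OTHER") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  label <- match.arg(label, dataset_labels)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     smi = "smi", sdf = "sdf", mol = "sdf",
                     csv = "csv", tsv = "csv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  out <- switch(
    format,
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      smi <- sub("[ \t].*$", "", trimws(lines))
      nm <- ifelse(grepl("[ \t]", trimws(lines)),
                   sub("^\\S+[ \t]+", "", trimws(lines)), "")
      tibble::tibble(name = nm, smiles_input = smi)
    },
    sdf = {
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
      smi <- vapply(ChemmineR::cid(sdfset), function(i) {
        block <- paste(ChemmineR::sdf2str(sdfset[[i]]), collapse = "\n")
        out <- tryCatch(
          suppressWarnings(ob_convert(block, "SDF", "CAN")),
          error = function(e) ""
        )
        sub("\t.*$", "", trimws(out))
      }, character(1))
      nm <- vapply(seq_along(sdfset), function(i) {
        ChemmineR::header(sdfset[[i]])[["Molecule_Name"]]
      }, character(1))
      nm[is.na(nm) | nm == "NA"] <- ""
      tibble::tibble(name = nm, smiles_input = smi)
    },
    csv = {
      df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      if (!smiles_col %in% names(df)) {
        stop("column '", smiles_col, "' not found in ", path, call. = FALSE)
      }
      nm <- if (!is.null(name_col) && name_col %in% names(df)) {
        as.character(df[[name_col]])
      } else ""
      ph <- if (!is.null(phase_col) && phase_col %in% names(df)) {
        as.integer(df[[phase_col]])
      } else NA_integer_
      smiles <- as.character(df[[smiles_col]])
      smiles[is.na(smiles)] <- ""
      tibble::tibble(name = nm, smiles_input = smiles, phase = ph)
    }
  )
  if (!"phase" %in% names(out)) out$phase <- NA_integer_
  out$name[is.na(out$name)] <- ""
  tibble::tibble(
    id = sprintf("M%05d", seq_len(nrow(out))),
    name = out$name,
    smiles_input = out$smiles_input,
    dataset_label = label,
    phase = out$phase
  )
}

# Standardize one SMILES: largest organic fragment, neutralized, canonical.
# Returns NA_character_ for empty/unparseable input or a fragment-free salt.
standardize_smiles <- function(smiles) {
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(NA_character_)
  frags <- tryCatch(
    suppressWarnings(ob_convert(paste0(smiles, "\n"), "SMI", "SMI",
                                ops = list(separate = ""))),
    error = function(e) NULL
  )
  if (is.null(frags)) return(NA_character_)
  frags <- sub("\t.*$", "", trimws(strsplit(frags, "\n")[[1]]))
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0) return(NA_character_)
  # organic = contains at least one carbon atom (checked on the parsed
  # graph, so chlorine does not count as carbon)
  info <- lapply(frags, function(f) {
    tryCatch(parse_mol(f), error = function(e) NULL)
  })
  sizes <- vapply(seq_along(frags), function(i) {
    m <- info[[i]]
    if (is.null(m) || !any(m$atoms$element == "C")) -1L else nrow(m$atoms)
  }, integer(1))
  if (all(sizes < 0)) return(NA_character_)
  best <- frags[[which.max(sizes)]]
  out <- tryCatch(
    suppressWarnings(ob_convert(paste0(best, "\n"), "SMI", "CAN",
                                ops = list(neutralize = ""))),
    error = function(e) ""
  )
  out <- sub("\t.*$", "", trimws(out))
  if (!nzchar(out)) NA_character_ else out
}

#' Standardize a molecule table
#'
#' Adds `smiles_std` (canonical SMILES of the neutralized largest organic
#' fragment) and `inchikey` (standard InChIKey of the standardized
#' structure). Counter-ions and solvent fragments are removed; records that
#' are empty, unparseable, or contain no organic fragment get `NA` in both
#' columns. The operation is idempotent on `smiles_std`.
#'
#' @param mols tibble with at least `smiles_input` (a plain character
#'   vector of SMILES also works).
#' @return the input tibble with `smiles_std` and `inchikey` columns.
#' @export
standardize_molecules <- function(mols) {
  if (is.character(mols)) {
    mols <- tibble::tibble(
      id = sprintf("M%05d", seq_along(mols)),
      name = "", smiles_input = mols,
      dataset_label = "OTHER", phase = NA_integer_
    )
  }
  stopifnot("smiles_input" %in% names(mols))
  std <- vapply(mols$smiles_input, standardize_smiles, character(1),
                USE.NAMES = FALSE)
  key <- rep(NA_character_, length(std))
  ok <- !is.na(std)
  if (any(ok)) key[ok] <- ob_inchikey(std[ok])
  dplyr::mutate(tibble::as_tibble(mols), smiles_std = std, inchikey = key)
}

#' Deduplicate standardized molecules
#'
#' Drops records whose standardization failed and keeps the first
#' occurrence of each InChIKey. Because the standard InChIKey is
#' stereo-sensitive, stereoisomers are retained as distinct molecules. The
#' standardization report is attached as attribute `"report"` and can be
#' retrieved with [standardization_report()].
#'
#' @param mols output of [standardize_molecules()].
#' @return deduplicated tibble with a `"report"` attribute.
#' @export
deduplicate_molecules <- function(mols) {
  stopifnot(all(c("smiles_std", "inchikey") %in% names(mols)))
  n_input <- nrow(mols)
  bad <- is.na(mols$smiles_std) | is.na(mols$inchikey)
  kept <- mols[!bad, , drop = FALSE]
  dup <- duplicated(kept$inchikey)
  out <- tibble::as_tibble(kept[!dup, , drop = FALSE])
  n_counterions <- sum(grepl(".", mols$smiles_input[!bad], fixed = TRUE))
  report <- tibble::tibble(
    n_input = n_input,
    n_counterions_removed = n_counterions,
    n_empty_or_unparseable = sum(bad),
    n_duplicates_removed = sum(dup),
    n_output = nrow(out)
  )
  attr(out, "report") <- report
  out
}

#' Retrieve the standardization report
#'
#' @param mols output of [deduplicate_molecules()].
#' @return one-row tibble with columns `n_input`, `n_counterions_removed`,
#'   `n_empty_or_unparseable`, `n_duplicates_removed`, `n_output`.
#' @export
standardization_report <- function(mols) {
  rep <- attr(mols, "report", exact = TRUE)
  if (is.null(rep)) stop("no standardization report attached", call. = FALSE)
  rep
}

#' Write a molecule table to CSV
#'
#' Columns are written in the fixed order `id`, `name`, `smiles_std`,
#' `inchikey`, `dataset_label`, `phase`.
#'
#' @param mols molecule tibble.
#' @param path output file.
#' @return `mols`, invisibly.
#' @export
write_molecules <- function(mols, path) {
  cols <- c("id", "name", "smiles_std", "inchikey", "dataset_label", "phase")
  stopifnot(all(cols %in% names(mols)))
  readr::write_csv(mols[, cols], path, progress = FALSE)
  invisible(mols)
}
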