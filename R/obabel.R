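# Low-level bridge to OpenBabel. All format conversions, canonicalization,
# InChIKey generation and the Wildman-Crippen logP / Ertl TPSA / molecular
# weight descriptors go through OpenBabel, either in-process (ChemmineOB)
# or through the obabel executable where the in-process bindings do not
# expose the feature (fingerprints).

# In-process conversion. `source` is the full text of the input (possibly
# multi-record); ops are OpenBabel generic options such as "neutralize".
ob_convert <- function(text, from, to, ops = NULL) {
  if (is.null(ops)) {
    return(ChemmineOB::convertFormat(from, to, source = text))
  }
  opt <- data.frame(names = names(ops), args = unname(unlist(ops)),
                    stringsAsFactors = FALSE)
  ChemmineOB::convertFormat(from, to, source = text, options = opt)
}

# OpenBabel aborts a multi-record conversion at the first bad record, so
# anything that may contain invalid structures is converted one record at
# a time. Returns NA for records that fail to convert.
ob_convert_each <- function(inputs, from, to, ops = NULL) {
  vapply(inputs, function(x) {
    out <- tryCatch(
      suppressWarnings(ob_convert(paste0(x, "\n"), from, to, ops)),
      error = function(e) ""
    )
    out <- sub("\t.*$", "", trimws(out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @keywords internal
ob_canonical <- function(smiles) {
  ob_convert_each(smiles, "SMI", "CAN")
}

# Standard InChIKeys (27-character hashes). NA on failure. Uses the obabel
# executable: the in-process conversion does not perceive stereochemistry,
# which would collapse stereoisomers to one key.
ob_inchikey <- function(smiles) {
  if (length(smiles) == 0) return(character())
  one <- function(s) {
    out <- suppressWarnings(
      system2(ob_executable(), c(shQuote(paste0("-:", s)), "-oinchikey"),
              stdout = TRUE, stderr = FALSE))
    out <- out[grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", out)]
    if (length(out) == 1) out else NA_character_
  }
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  writeLines(smiles, smi)
  out <- suppressWarnings(
    system2(ob_executable(), c(smi, "-oinchikey", "-e"),
            stdout = TRUE, stderr = FALSE))
  out <- out[grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", out)]
  if (length(out) == length(smiles)) return(out)
  # some record failed to convert: fall back to per-molecule calls to keep
  # the input/output alignment
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}

# logP (Wildman-Crippen), TPSA (Ertl) and molecular weight for a vector of
# valid SMILES. Molecules must already be standardized/parseable.
ob_lipophilicity_panel <- function(smiles) {
  if (length(smiles) == 0) {
    return(tibble::tibble(ClogP = numeric(), TPSA = numeric(), MW = numeric()))
  }
  rows <- lapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ob_convert(paste0(s, "\n"), "SMI", "SMI",
                                  ops = list(append = "logP TPSA MW"))),
      error = function(e) ""
    )
    # output: "<smiles>\t<logP> <TPSA> <MW>"
    fields <- strsplit(trimws(out), "[\t ]+")[[1]]
    n <- length(fields)
    if (n < 4) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(fields[(n - 2):n])
  })
  m <- do.call(rbind, rows)
  tibble::tibble(ClogP = m[, 1], TPSA = m[, 2], MW = m[, 3])
}

# Locate the obabel executable (needed only for fingerprints).
ob_executable <- function() {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) {
    stop("the 'obabel' executable is required but was not found on PATH",
         call. = FALSE)
  }
  unname(exe)
}

#' Binary fingerprints via OpenBabel
#'
#' Computes 166-bit MACCS structural keys or ECFP4 circular fingerprints
#' (radius 2) for a set of molecules.
#'
#' @param smiles character vector of valid SMILES.
#' @param kind `"maccs"` or `"ecfp4"`.
#' @return logical matrix, one row per molecule.
#' @keywords internal
ob_fingerprints <- function(smiles, kind = c("maccs", "ecfp4")) {
  kind <- match.arg(kind)
  fpname <- switch(kind, maccs = "MACCS", ecfp4 = "ECFP4")
  stopifnot(length(smiles) >= 1)
  ids <- sprintf("m%08d", seq_along(smiles))
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  writeLines(paste(smiles, ids), smi)
  out <- suppressWarnings(
    system2(ob_executable(), c(smi, "-ofpt", "-xf", fpname, "-xh", "-e"),
            stdout = TRUE, stderr = FALSE)
  )
  # FPT hex output: one ">id ..." header per molecule followed by lines of
  # 8-digit hex words (most significant word first).
  hdr <- grep("^>", out)
  if (length(hdr) != length(smiles)) {
    stop("fingerprint generation failed for ",
         length(smiles) - length(hdr), " molecule(s)", call. = FALSE)
  }
  got <- sub("^>\\s*(\\S+).*$", "\\1", out[hdr])
  if (!identical(got, ids)) stop("fingerprint output out of order", call. = FALSE)
  bounds <- c(hdr, length(out) + 1L)
  rows <- lapply(seq_along(hdr), function(i) {
    block <- out[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    words <- unlist(strsplit(trimws(paste(block, collapse = " ")), "\\s+"))
    # keep only 8-digit hex words; fpt interleaves commentary lines
    words <- words[grepl("^[0-9a-fA-F]{8}$", words)]
    hex_words_to_bits(words)
  })
  n_bits <- max(lengths(rows))
  mat <- t(vapply(rows, function(r) {
    length(r) <- n_bits
    r[is.na(r)] <- FALSE
    r
  }, logical(n_bits)))
  rownames(mat) <- NULL
  mat
}

# Expand hex words into a logical bit vector. The mapping from hex digit to
# column is fixed but arbitrary: Tanimoto coefficients only require that the
# same mapping is applied to every molecule. MACCS keys therefore occupy 166
# of the returned columns; the remainder are identically zero.
hex_words_to_bits <- function(words) {
  halves <- as.vector(rbind(substring(words, 1, 4), substring(words, 5, 8)))
  vals <- strtoi(halves, base = 16L)
  unlist(lapply(vals, function(v) as.logical(bitwAnd(v, 2^(15:0)))))
}

# Locate a file shipped with the package, falling back to the source tree
# (inst/) when the package is loaded without being installed.
pkg_file <- function(...) {
  p <- system.file(..., package = "kinasespace")
  if (nzchar(p)) return(p)
  local <- file.path("inst", ...)
  if (file.exists(local)) return(local)
  stop("packaged file not found: ", file.path(...), call. = FALSE)
}
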