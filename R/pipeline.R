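# End-to-end orchestration: run every analysis stage on a labelled
# molecule table and emit a report bundle of tidy tables that mirror the
# comparison tables of a PKI chemical-space study (violation tables,
# guideline ranges, PCA outputs, PMI table, scaffold diversity, ring
# frequency tables).

#' Run the full analysis pipeline
#'
#' @param mols molecule tibble (already read); it is standardized and
#'   deduplicated first unless it already carries `smiles_std`/`inchikey`.
#' @param stages character vector among `"descriptors"`, `"pca"`,
#'   `"pmi"`, `"scaffolds"`, `"rings"`, `"similarity"`.
#' @param sd_mult guideline width in standard deviations.
#' @param n_confs,seed conformer stage parameters.
#' @param butina_threshold Tanimoto distance threshold for clustering.
#' @return a `kin_report` list of tidy tables plus a `manifest` recording
#'   parameters, seeds and stage completion; failed stages are recorded
#'   in the manifest and leave their slot `NULL` (bundle marked partial).
#' @export
run_pipeline <- function(mols,
                         stages = c("descriptors", "pca", "pmi", "scaffolds",
                                    "rings", "similarity"),
                         sd_mult = 2, n_confs = 10, seed = 42,
                         butina_threshold = 0.6) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!all(c("smiles_std", "inchikey") %in% names(mols))) {
    mols <- deduplicate_molecules(standardize_molecules(mols))
  }
  bundle <- list(molecules = mols)
  status <- list()
  run_stage <- function(name, expr) {
    if (!name %in% stages) {
      status[[name]] <<- "skipped"
      return(NULL)
    }
    tryCatch({
      val <- force(expr)
      status[[name]] <<- "ok"
      val
    }, error = function(e) {
      status[[name]] <<- paste("failed:", conditionMessage(e))
      NULL
    })
  }

  desc <- run_stage("descriptors", compute_descriptors(mols))
  if (!is.null(desc)) {
    bundle$descriptors <- desc
    bundle$rule_profiles <- rule_profile(desc)
    bundle$lipinski_distribution <- violation_distribution(bundle$rule_profiles,
                                                           "lipinski")
    bundle$veber_distribution <- violation_distribution(bundle$rule_profiles,
                                                        "veber")
    bundle$guidelines <- derive_guidelines(desc, k_sd = sd_mult)
  }
  if (!is.null(desc)) {
    pca <- run_stage("pca", {
      model <- fit_pca(desc)
      list(model = model,
           projection = project_pca(model, desc),
           correlation_circle = correlation_circle(model),
           explained = tidy(model, "eigenvalues"),
           contributions = tidy(model, "contributions"))
    })
    if (!is.null(pca)) bundle$pca <- pca
  } else {
    status$pca <- "skipped"
  }
  pmi <- run_stage("pmi", pmi_table(mols, n_confs = n_confs, seed = seed))
  if (!is.null(pmi)) bundle$pmi <- pmi
  sc <- run_stage("scaffolds", {
    list(table = scaffold_table(mols), stats = diversity_stats(mols))
  })
  if (!is.null(sc)) bundle$scaffolds <- sc
  rings <- run_stage("rings", {
    systems <- ring_system_table(mols)
    list(
      systems = systems,
      unpositioned = bicycle_frequency(systems, "unpositioned"),
      positioned = bicycle_frequency(systems, "positioned"),
      prevalence = bicycle_prevalence(mols, systems)
    )
  })
  if (!is.null(rings)) bundle$rings <- rings
  sim <- run_stage("similarity", {
    list(stats = pairwise_similarity(mols, "maccs"),
         clusters = cluster_butina(mols, threshold = butina_threshold))
  })
  if (!is.null(sim)) bundle$similarity <- sim

  bundle$manifest <- list(
    n_molecules = nrow(mols),
    stages = status,
    parameters = list(sd_mult = sd_mult, n_confs = n_confs, seed = seed,
                      butina_threshold = butina_threshold),
    complete = !any(grepl("^failed", unlist(status))),
    package_version = as.character(utils::packageVersion("kinasespace"))
  )
  structure(bundle, class = "kin_report")
}

#' @export
print.kin_report <- function(x, ...) {
  cat("kinasespace report bundle:", x$manifest$n_molecules, "molecules\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-12s %s\n", s, x$manifest$stages[[s]]))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes each table of the bundle as CSV (frequency summaries and the
#' manifest as JSON) into `dir`. Rerunning the same pipeline writes
#' byte-identical files.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return the paths written, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "kin_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(obj, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  put_json <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
  }
  put(bundle$molecules, "molecules")
  if (!is.null(bundle$descriptors)) {
    put(bundle$descriptors, "descriptors")
    put(bundle$lipinski_distribution, "lipinski_distribution")
    put(bundle$veber_distribution, "veber_distribution")
    put(bundle$guidelines, "guidelines")
  }
  if (!is.null(bundle$pca)) {
    put(bundle$pca$explained, "pca_explained")
    put(bundle$pca$contributions, "pca_contributions")
    put(bundle$pca$correlation_circle, "pca_correlation_circle")
    put(bundle$pca$projection$scores, "pca_scores")
  }
  if (!is.null(bundle$pmi)) put(bundle$pmi, "pmi")
  if (!is.null(bundle$scaffolds)) {
    put(bundle$scaffolds$table, "scaffolds")
    put(bundle$scaffolds$stats, "scaffold_stats")
  }
  if (!is.null(bundle$rings)) {
    put(bundle$rings$systems, "ring_systems")
    put(bundle$rings$unpositioned, "bicycles_unpositioned")
    put(bundle$rings$positioned, "bicycles_positioned")
    put_json(list(
      bicycle_prevalence = bundle$rings$prevalence,
      unpositioned = as.list(frequency_summary(bundle$rings$unpositioned)),
      positioned = as.list(frequency_summary(bundle$rings$positioned))
    ), "ring_summary")
  }
  if (!is.null(bundle$similarity)) {
    put(bundle$similarity$stats, "similarity_stats")
    put(bundle$similarity$clusters, "clusters")
  }
  put_json(bundle$manifest, "manifest")
  invisible(paths)
}

#' Read a pipeline run configuration
#'
#' YAML keys: `input` (path), `format`, `smiles_col`, `label`, `stages`,
#' `sd_mult`, `n_confs`, `seed`, `butina_threshold`, `out_dir`.
#'
#' @param path YAML file.
#' @return a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    format = "auto", smiles_col = "smiles", label = "OTHER",
    stages = c("descriptors", "pca", "pmi", "scaffolds", "rings",
               "similarity"),
    sd_mult = 2, n_confs = 10, seed = 42, butina_threshold = 0.6,
    out_dir = "kinasespace_report"
  )
  utils::modifyList(defaults, cfg)
}
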