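#' Read an ASV table from TSV counts, TSV taxonomy and a newick tree
#'
#' The counts TSV has an `asv_id` column plus one integer column per
#' library; the taxonomy TSV has `asv_id` and `lineage`; library metadata is
#' parsed from a companion TSV when given, otherwise from library ids of the
#' form `<treatment>_<time>h`. Duplicate ASV ids, non-integer counts and
#' ASVs absent from the tree are specific errors.
#'
#' @param counts_path,taxonomy_path,tree_path File paths; `tree_path` may be
#'   NULL for tables without a phylogeny.
#' @param library_meta_path Optional TSV with `library_id`, `treatment`,
#'   `timepoint_h`.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(counts_path, taxonomy_path, tree_path = NULL,
                           library_meta_path = NULL) {
  raw <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (!"asv_id" %in% names(raw)) {
    stop("counts file needs an `asv_id` column", call. = FALSE)
  }
  if (anyDuplicated(raw$asv_id)) {
    stop(sprintf("duplicate ASV id(s): %s",
                 paste(unique(raw$asv_id[duplicated(raw$asv_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(raw[setdiff(names(raw), "asv_id")])
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  rownames(m) <- raw$asv_id
  taxonomy <- readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  tree <- if (!is.null(tree_path)) ape::read.tree(tree_path) else NULL
  meta <- if (!is.null(library_meta_path)) {
    readr::read_tsv(library_meta_path, show_col_types = FALSE)
  } else {
    ids <- colnames(m)
    tp <- suppressWarnings(as.numeric(sub("^.*_(\\d+)h$", "\\1", ids)))
    trt <- sub("_\\d+h$", "", ids)
    trt[is.na(tp)] <- ifelse(grepl("t0|sediment", ids[is.na(tp)]),
                             "sediment_t0", trt[is.na(tp)])
    tp[is.na(tp)] <- 0
    tibble::tibble(library_id = ids, treatment = trt, timepoint_h = tp)
  }
  asv_table(m, meta, taxonomy, tree)
}

#' Write an ASV table to TSV counts, TSV taxonomy, TSV metadata and newick
#'
#' @param table An [asv_table()].
#' @param counts_path,taxonomy_path,library_meta_path,tree_path Output
#'   paths; `tree_path` is skipped when the table has no tree.
#' @return Invisibly, the table.
#' @export
write_asv_table <- function(table, counts_path, taxonomy_path,
                            library_meta_path = NULL, tree_path = NULL) {
  stopifnot(inherits(table, "asv_table"))
  df <- tibble::as_tibble(table$counts, rownames = "asv_id")
  readr::write_tsv(df, counts_path)
  readr::write_tsv(table$taxonomy, taxonomy_path)
  if (!is.null(library_meta_path)) {
    readr::write_tsv(table$library_meta, library_meta_path)
  }
  if (!is.null(tree_path) && !is.null(table$tree)) {
    ape::write.tree(table$tree, tree_path)
  }
  invisible(table)
}

#' Read/write concentration, SRR and metabolite CSV tables
#'
#' Plain UTF-8 comma-separated tables with the column layouts used across
#' the package: concentrations `(time_h, analyte, mean_mM, sd_mM, n)`, SRR
#' `(time_h, rate_nmol_cm3_d[, replicate])`, metabolites
#' `(metabolite, treatment, timepoint_h, replicate, intensity)`.
#'
#' @param path File path.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_concentrations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname table_io
#' @param x Table to write.
#' @export
write_concentrations <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_srr <- function(path) readr::read_csv(path, show_col_types = FALSE)

#' @rdname table_io
#' @export
write_srr <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_metabolites <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname table_io
#' @export
write_metabolites <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Read or write a simulation scenario as YAML
#'
#' @param path YAML file path.
#' @return A [simulation_config()] (reader); the config invisibly (writer).
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  pops <- lapply(y$populations, function(p) {
    population_spec(
      name = p$name, n0 = p$n0, doubling_time_h = p$doubling_time_h,
      onset_h = p$onset_h %||% 0, cs_srr = p$cs_srr %||% 0,
      cs_turnover = p$cs_turnover %||% 0,
      substrates = if (length(p$substrates)) unlist(p$substrates),
      products = if (length(p$products)) unlist(p$products),
      growth_end_h = p$growth_end_h %||% Inf,
      decay_halflife_h = p$decay_halflife_h %||% Inf
    )
  })
  simulation_config(
    populations = pops,
    time_grid = y$time_grid %||% default_time_grid(),
    sulfate_init = y$sulfate_init %||% 15.6,
    vfa_init = if (length(y$vfa_init)) unlist(y$vfa_init) else
      default_vfa_init(),
    slurry_sediment_fraction = y$slurry_sediment_fraction %||% 1,
    noise_cv = y$noise_cv %||% 0.05,
    seed = y$seed %||% 1L,
    sequencing_depth = y$sequencing_depth %||% 24000L,
    n_background_asvs = y$n_background_asvs %||% 150L
  )
}

#' @rdname read_scenario
#' @param config A [simulation_config()].
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  serialize_pop <- function(p) {
    out <- unclass(p)
    out$substrates <- as.list(p$substrates)
    out$products <- as.list(p$products)
    out$growth_end_h <- if (is.finite(p$growth_end_h)) p$growth_end_h else
      NULL
    out$decay_halflife_h <- if (is.finite(p$decay_halflife_h))
      p$decay_halflife_h else NULL
    out
  }
  y <- list(
    populations = lapply(config$populations, serialize_pop),
    time_grid = config$time_grid,
    sulfate_init = config$sulfate_init,
    vfa_init = as.list(config$vfa_init),
    slurry_sediment_fraction = config$slurry_sediment_fraction,
    noise_cv = config$noise_cv,
    seed = config$seed,
    sequencing_depth = config$sequencing_depth,
    n_background_asvs = config$n_background_asvs
  )
  yaml::write_yaml(y, path, precision = 15L)
  invisible(config)
}

#' Write every component of a simulated experiment to a directory
#'
#' Emits `srr.csv`, `concentrations.csv`, `asv_counts.tsv`, `taxonomy.tsv`,
#' `library_meta.tsv`, `tree.nwk`, `metabolites.csv` and `truth.yml` (the
#' generating configuration); components not present are skipped.
#'
#' @param experiment A `simulated_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "simulated_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)
  p <- file.path(dir, "srr.csv")
  write_srr(experiment$srr_replicates, p); add(p)
  p <- file.path(dir, "concentrations.csv")
  write_concentrations(experiment$concentrations, p); add(p)
  if (!is.null(experiment$asv_table)) {
    paths <- file.path(dir, c("asv_counts.tsv", "taxonomy.tsv",
                              "library_meta.tsv", "tree.nwk"))
    write_asv_table(experiment$asv_table, paths[1], paths[2], paths[3],
                    paths[4])
    written <- c(written, paths[file.exists(paths)])
  }
  if (!is.null(experiment$metabolites)) {
    p <- file.path(dir, "metabolites.csv")
    write_metabolites(experiment$metabolites, p); add(p)
  }
  p <- file.path(dir, "truth.yml")
  write_scenario(experiment$truth, p); add(p)
  invisible(written)
}
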