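#' Construct an ASV count table with metadata, taxonomy and phylogeny
#'
#' The central amplicon container: a non-negative integer count matrix
#' (ASVs x libraries), per-library metadata (treatment and timepoint), a
#' ranked lineage string per ASV, and an optional rooted phylogeny whose
#' leaves cover all ASV ids (required for UniFrac). Triplicate slurries are
#' pooled before DNA extraction in this design, so each treatment x timepoint
#' is a single library.
#'
#' @param counts Integer matrix, ASVs in rows (rownames = ASV ids), libraries
#'   in columns (colnames = library ids).
#' @param library_meta Data frame with columns `library_id`, `treatment`
#'   (one of `"amended"`, `"unamended"`, `"sediment_t0"`), `timepoint_h`.
#' @param taxonomy Data frame with columns `asv_id`, `lineage`
#'   (semicolon-separated ranks: domain;phylum;class;order;family;genus).
#' @param tree A rooted `phylo` with branch lengths, or NULL.
#' @return Object of class `asv_table`.
#' @export
asv_table <- function(counts, library_meta, taxonomy, tree = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs ASV rownames and library colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate ASV ids in count matrix", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (any(colSums(counts) == 0)) {
    stop(sprintf("library with zero total reads: %s",
                 paste(colnames(counts)[colSums(counts) == 0],
                       collapse = ", ")), call. = FALSE)
  }
  library_meta <- tibble::as_tibble(library_meta)
  stopifnot(all(c("library_id", "treatment", "timepoint_h") %in%
                  names(library_meta)))
  if (!setequal(library_meta$library_id, colnames(counts))) {
    stop("library metadata does not match count matrix columns",
         call. = FALSE)
  }
  if (any(library_meta$timepoint_h < 0)) {
    stop("timepoints must be non-negative", call. = FALSE)
  }
  taxonomy <- tibble::as_tibble(taxonomy)
  stopifnot(all(c("asv_id", "lineage") %in% names(taxonomy)))
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    missing <- setdiff(rownames(counts), tree$tip.label)
    if (length(missing)) {
      stop(sprintf("ASV(s) missing from tree: %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(counts = counts, library_meta = library_meta,
                 taxonomy = taxonomy, tree = tree),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d ASVs x %d libraries%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$tree)) "" else " (+tree)"))
  invisible(x)
}

#' Per-library relative abundances
#' @param table An [asv_table()].
#' @return Numeric matrix of the same shape as `table$counts`, columns
#'   summing to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  sweep(table$counts, 2, colSums(table$counts), "/")
}

#' Occurrence filter: is an ASV present in a library?
#'
#' An ASV counts as present in a library when its relative sequence abundance
#' is at least `threshold` (default 0.1%, i.e. at least 24 reads in a
#' 24,000-read library) -- a guard against platform carry-over contamination.
#'
#' @param table An [asv_table()].
#' @param threshold Relative-abundance cutoff in (0, 1); presence is
#'   non-strict (`>= threshold`).
#' @return Logical matrix (ASVs x libraries).
#' @export
filter_occurrence <- function(table, threshold = 0.001) {
  assert_number(threshold, "threshold", 0, 1, strict_lower = TRUE)
  if (threshold >= 1) stop("`threshold` must be in (0, 1)", call. = FALSE)
  relative_abundance(table) >= threshold
}

#' Classify ASVs enriched during incubation
#'
#' An ASV represents an enriched population when it is absent (below
#' `occ_threshold` relative abundance) in every unheated sediment library and
#' present at strictly more than `enr_threshold` relative abundance in at
#' least one incubated library. `incubated_scope` controls whether the >1%
#' clause may be satisfied in any incubated library (`"union"`, default) or
#' must hold within each treatment separately (`"per_treatment"`, in which
#' case the ASV must clear the bar in every treatment where it occurs at
#' all).
#'
#' @param table An [asv_table()] with at least one `sediment_t0` and one
#'   incubated library.
#' @param occ_threshold Occurrence cutoff (non-strict, default 0.001).
#' @param enr_threshold Enrichment cutoff (strict, default 0.01).
#' @param incubated_scope `"union"` or `"per_treatment"`.
#' @return Tibble with one row per ASV: `asv_id`, `present_t0`,
#'   `max_incubated_abundance`, `enriched`, `first_detection_h`.
#' @export
classify_enriched <- function(table, occ_threshold = 0.001,
                              enr_threshold = 0.01,
                              incubated_scope = c("union", "per_treatment")) {
  stopifnot(inherits(table, "asv_table"))
  incubated_scope <- match.arg(incubated_scope)
  meta <- table$library_meta
  t0_libs <- meta$library_id[meta$treatment == "sediment_t0"]
  inc_libs <- meta$library_id[meta$treatment != "sediment_t0"]
  if (!length(t0_libs)) {
    stop("no sediment_t0 libraries in the table", call. = FALSE)
  }
  if (!length(inc_libs)) {
    stop("no incubated libraries in the table", call. = FALSE)
  }
  rel <- relative_abundance(table)
  present <- rel >= occ_threshold

  present_t0 <- apply(present[, t0_libs, drop = FALSE], 1, any)
  max_inc <- apply(rel[, inc_libs, drop = FALSE], 1, max)
  if (incubated_scope == "union") {
    clears <- max_inc > enr_threshold
  } else {
    trts <- unique(meta$treatment[meta$treatment != "sediment_t0"])
    per <- vapply(trts, function(trt) {
      libs <- meta$library_id[meta$treatment == trt]
      apply(rel[, libs, drop = FALSE], 1, max)
    }, numeric(nrow(rel)))
    occurs <- per >= occ_threshold
    clears <- vapply(seq_len(nrow(rel)), function(i) {
      idx <- occurs[i, ]
      any(idx) && all(per[i, idx] > enr_threshold)
    }, logical(1))
  }

  first_det <- vapply(rownames(rel), function(a) {
    hit <- inc_libs[present[a, inc_libs]]
    if (!length(hit)) return(NA_real_)
    min(meta$timepoint_h[match(hit, meta$library_id)])
  }, numeric(1), USE.NAMES = FALSE)

  tibble::tibble(
    asv_id = rownames(rel),
    present_t0 = present_t0,
    max_incubated_abundance = max_inc,
    enriched = !present_t0 & clears,
    first_detection_h = first_det
  )
}

#' Rarefy libraries to equal depth by subsampling without replacement
#'
#' Each library is an independent random draw of `depth` reads without
#' replacement from its observed reads (multivariate hypergeometric), so all
#' column sums equal `depth` exactly. One draw is taken per library; the
#' result is reproducible under `seed`.
#'
#' @param table An [asv_table()] whose every library total is >= `depth`.
#' @param depth Target reads per library (e.g. 16667).
#' @param seed Integer seed.
#' @return A rarefied [asv_table()] (metadata, taxonomy, tree unchanged).
#' @export
rarefy_counts <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "asv_table"))
  assert_number(depth, "depth", 0, strict_lower = TRUE)
  depth <- as.integer(depth)
  totals <- colSums(table$counts)
  short <- totals < depth
  if (any(short)) {
    stop(sprintf("library total below rarefaction depth %d: %s", depth,
                 paste(names(totals)[short], collapse = ", ")),
         call. = FALSE)
  }
  counts <- with_seed_if(seed, {
    apply(table$counts, 2, function(x) {
      if (sum(x) == depth) return(x)
      reads <- rep.int(seq_along(x), x)
      drawn <- sample(reads, depth, replace = FALSE)
      tabulate(drawn, nbins = length(x))
    })
  })
  rownames(counts) <- rownames(table$counts)
  asv_table(counts, table$library_meta, table$taxonomy, table$tree)
}

#' Aggregate relative abundances at a taxonomic rank
#'
#' Lineage strings are split on `;` into domain, phylum, class, order,
#' family, genus; counts are pooled per taxon at the requested rank and
#' normalized within each library. Empty or missing rank labels are pooled
#' as `"unclassified"`.
#'
#' @param table An [asv_table()].
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Tidy tibble: `taxon`, `library_id`, `fraction`, joined with the
#'   library metadata.
#' @export
aggregate_taxonomy <- function(table, rank = "class") {
  stopifnot(inherits(table, "asv_table"))
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  rank <- match.arg(rank, ranks)
  parts <- strsplit(table$taxonomy$lineage, ";", fixed = TRUE)
  lab <- vapply(parts, function(p) {
    v <- p[match(rank, ranks)]
    if (is.na(v) || !nzchar(trimws(v))) "unclassified" else trimws(v)
  }, character(1))
  lab <- lab[match(rownames(table$counts), table$taxonomy$asv_id)]
  lab[is.na(lab)] <- "unclassified"
  pooled <- rowsum(table$counts, group = lab)
  frac <- sweep(pooled, 2, colSums(pooled), "/")
  out <- tibble::as_tibble(as.table(frac), .name_repair = "minimal")
  names(out) <- c("taxon", "library_id", "fraction")
  dplyr::left_join(out, table$library_meta, by = "library_id")
}
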