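#' Default enriched-ASV roster for the simulated community
#'
#' Twenty-one spore-forming Bacillota ASVs that bloom in heated slurries:
#' eleven fermentative Clostridia (detected within 24 h), four early
#' Desulfohalotomaculum and four late Desulfallas sulfate reducers, and two
#' Peptococcaceae that rise with succinate turnover. Per-treatment maximum
#' relative abundances and logistic midpoints shape each trajectory; a zero
#' maximum means the ASV never appears in that treatment.
#'
#' @return Tibble with columns `asv_id`, `class`, `genus`, `amended_max`,
#'   `unamended_max`, `midpoint_h`.
#' @export
default_bloomer_roster <- function() {
  tibble::tribble(
    ~asv_id,  ~class,             ~genus,                  ~amended_max, ~unamended_max, ~midpoint_h,
    "ASV_1",  "Clostridia",       "Proteiniborus",         0.10,  0.12, 15,
    "ASV_4",  "Clostridia",       "Clostridiisalibacter",  0,     0.24, 12,
    "ASV_32", "Clostridia",       "Defluviitalea",         0.03,  0.05, 14,
    "ASV_9",  "Clostridia",       "Tepidibacter",          0.025, 0.04, 16,
    "ASV_11", "Clostridia",       "Caloranaerobacter",     0.02,  0.03, 14,
    "ASV_13", "Clostridia",       "Caminicella",           0.02,  0.03, 18,
    "ASV_15", "Clostridia",       "Clostridiisalibacter",  0.015, 0.025, 20,
    "ASV_20", "Clostridia",       "Proteiniborus",         0.03,  0.05, 18,
    "ASV_27", "Clostridia",       "Tepidibacter",          0.02,  0.04, 22,
    "ASV_35", "Clostridia",       "Defluviitalea",         0.015, 0.03, 20,
    "ASV_41", "Clostridia",       "Caminicella",           0.015, 0.025, 24,
    "ASV_6",  "Desulfotomaculia", "Desulfohalotomaculum",  0.155, 0.025, 18,
    "ASV_12", "Desulfotomaculia", "Desulfohalotomaculum",  0.018, 0, 20,
    "ASV_19", "Desulfotomaculia", "Desulfohalotomaculum",  0.016, 0, 22,
    "ASV_21", "Desulfotomaculia", "Desulfohalotomaculum",  0.015, 0, 24,
    "ASV_7",  "Desulfotomaculia", "Desulfallas",           0.045, 0, 100,
    "ASV_10", "Desulfotomaculia", "Desulfallas",           0.04,  0, 105,
    "ASV_24", "Desulfotomaculia", "Desulfallas",           0.018, 0, 110,
    "ASV_63", "Desulfotomaculia", "Desulfallas",           0.016, 0, 115,
    "ASV_17", "Desulfotomaculia", "Peptococcaceae",        0.02,  0, 70,
    "ASV_58", "Desulfotomaculia", "Peptococcaceae",        0.018, 0, 75
  )
}

# logistic rise from the time-zero baseline, anchored so the share at t = 0
# equals exactly `base`
bloom_share <- function(t, base, max_share, midpoint, scale = 4) {
  if (max_share <= 0) return(rep(0, length(t)))
  l <- stats::plogis((t - midpoint) / scale)
  l0 <- stats::plogis(-midpoint / scale)
  base + (max_share - base) * pmax(0, (l - l0) / (1 - l0))
}

#' Build the default community relative-abundance trajectories
#'
#' Emulates a rare biosphere: `n_background_asvs` background taxa drawn from
#' a log-normal rank-abundance distribution hold >= 99% of the community at
#' time zero, while each bloomer starts below 0.1% and follows a logistic
#' trajectory to its per-treatment maximum. Background shares are rescaled at
#' every timepoint so each library's relative abundances sum to one. One
#' unheated sediment library (t = 0) plus 13 timepoints for each treatment
#' give 27 libraries.
#'
#' @param config A [simulation_config()]; supplies the seed, background ASV
#'   count and sequencing depth.
#' @param roster Bloomer roster, see [default_bloomer_roster()].
#' @param timepoints Library timepoints (h) for each incubated treatment.
#' @param baseline_share Time-zero relative abundance of every bloomer.
#' @return A list of class `community_trajectories` with elements `libraries`
#'   (tibble: library_id, treatment, timepoint_h), `shares` (ASV x library
#'   matrix), and `taxonomy` (tibble: asv_id, lineage).
#' @export
default_community_trajectories <- function(config,
                                           roster = default_bloomer_roster(),
                                           timepoints = c(12, 18, 24, 30, 36,
                                                          48, 54, 60, 72, 96,
                                                          120, 144, 216),
                                           baseline_share = 2e-4) {
  stopifnot(inherits(config, "simulation_config"))
  n_bg <- config$n_background_asvs
  bg_ids <- sprintf("BG_%03d", seq_len(n_bg))
  bg_weights <- with_seed_if(config$seed + 7L,
                             stats::rlnorm(n_bg, meanlog = 0, sdlog = 1.2))
  bg_rel <- bg_weights / sum(bg_weights)

  libraries <- tibble::tibble(
    library_id = c("sediment_t0",
                   sprintf("amended_%03dh", timepoints),
                   sprintf("unamended_%03dh", timepoints)),
    treatment = c("sediment_t0", rep("amended", length(timepoints)),
                  rep("unamended", length(timepoints))),
    timepoint_h = c(0, timepoints, timepoints)
  )

  asv_ids <- c(roster$asv_id, bg_ids)
  shares <- matrix(0, length(asv_ids), nrow(libraries),
                   dimnames = list(asv_ids, libraries$library_id))
  for (j in seq_len(nrow(libraries))) {
    t <- libraries$timepoint_h[j]
    trt <- libraries$treatment[j]
    bl <- vapply(seq_len(nrow(roster)), function(i) {
      mx <- switch(trt,
                   sediment_t0 = 0,
                   amended = roster$amended_max[i],
                   unamended = roster$unamended_max[i])
      if (trt == "sediment_t0") {
        if (max(roster$amended_max[i], roster$unamended_max[i]) > 0)
          baseline_share else 0
      } else if (mx > 0) {
        bloom_share(t, baseline_share, mx, roster$midpoint_h[i])
      } else 0
    }, numeric(1))
    shares[roster$asv_id, j] <- bl
    shares[bg_ids, j] <- (1 - sum(bl)) * bg_rel
  }

  bg_lineages <- with_seed_if(config$seed + 8L, {
    phyla <- c("Actinobacteriota", "Bacteroidota", "Campylobacterota",
               "Cyanobacteria", "Desulfobacterota", "Pseudomonadota")
    ph <- sample(phyla, n_bg, replace = TRUE)
    cls <- paste0(ph, "_class")
    # a handful of unassigned lineages exercise the "unclassified" pool
    drop <- sample(n_bg, max(3L, n_bg %/% 30L))
    cls[drop] <- ""
    sprintf("Bacteria;%s;%s;;;", ph, cls)
  })
  taxonomy <- tibble::tibble(
    asv_id = asv_ids,
    lineage = c(sprintf("Bacteria;Bacillota;%s;;%s;%s",
                        roster$class,
                        ifelse(roster$genus == "Peptococcaceae",
                               "Peptococcaceae", ""),
                        ifelse(roster$genus == "Peptococcaceae",
                               "", roster$genus)),
                bg_lineages)
  )

  structure(list(libraries = libraries, shares = shares, taxonomy = taxonomy),
            class = "community_trajectories")
}

#' Draw multinomial ASV count libraries from relative-abundance trajectories
#'
#' Each library is an independent multinomial draw of `sequencing_depth`
#' reads from its timepoint's relative-abundance vector. A matching taxonomy
#' table and a random coalescent tree over all ASVs are attached.
#'
#' @param config A [simulation_config()] (depth and seed).
#' @param trajectories A `community_trajectories` object, or any list with
#'   `libraries`, `shares` and optionally `taxonomy` in the same shape.
#' @return An [asv_table()].
#' @export
#' @examples
#' cfg <- default_scenario(noise_cv = 0, seed = 3)
#' tab <- simulate_asv_counts(cfg, default_community_trajectories(cfg))
#' colSums(tab$counts)[1:3]
simulate_asv_counts <- function(config, trajectories) {
  stopifnot(inherits(config, "simulation_config"))
  depth <- config$sequencing_depth
  if (depth <= 0) stop("sequencing depth must be positive", call. = FALSE)
  shares <- trajectories$shares
  libs <- trajectories$libraries
  if (is.null(rownames(shares)) ||
      !identical(colnames(shares), libs$library_id)) {
    stop("trajectory share columns must match library ids", call. = FALSE)
  }
  csum <- colSums(shares)
  if (any(abs(csum - 1) > 1e-9)) {
    stop("relative abundances must sum to 1 per library", call. = FALSE)
  }
  if (any(shares < 0)) stop("relative abundances must be >= 0", call. = FALSE)

  counts <- with_seed_if(config$seed + 11L, {
    m <- vapply(seq_len(ncol(shares)),
                function(j) stats::rmultinom(1, depth, shares[, j])[, 1],
                integer(nrow(shares)))
    matrix(m, nrow(shares), ncol(shares))
  })
  dimnames(counts) <- dimnames(shares)

  taxonomy <- trajectories$taxonomy %||%
    tibble::tibble(asv_id = rownames(shares),
                   lineage = "Bacteria;;;;;")
  tree <- if (nrow(shares) >= 2L) {
    with_seed_if(config$seed + 12L,
                 ape::rcoal(nrow(shares), tip.label = rownames(shares)))
  } else NULL

  asv_table(counts = counts, library_meta = libs, taxonomy = taxonomy,
            tree = tree)
}
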