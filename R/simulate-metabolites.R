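#' Temporal pattern labels understood by the metabolite simulator
#' @noRd
METABOLITE_PATTERNS <- c("decrease", "increase_then_decrease", "increase",
                         "fluctuate", "flat")

#' Default untargeted-metabolite roster
#'
#' Amino acids produced by protein/peptide breakdown and consumed again
#' (rise-then-fall peaking at 12 h in amended slurries, monotone decline in
#' unamended ones), fluctuating degradation intermediates (fumarate,
#' pyruvate), and 2-oxoglutarate increasing in all slurries.
#'
#' @return Tibble with columns `metabolite`, `class`, `amended`, `unamended`
#'   (pattern labels per treatment).
#' @export
default_metabolite_profiles <- function() {
  tibble::tribble(
    ~metabolite,       ~class,          ~amended,                  ~unamended,
    "L-citrulline",    "amino acid",    "increase_then_decrease",  "decrease",
    "L-histidine",     "amino acid",    "increase_then_decrease",  "decrease",
    "L-serine",        "amino acid",    "increase_then_decrease",  "decrease",
    "L-asparagine",    "amino acid",    "decrease",                "increase_then_decrease",
    "L-threonine",     "amino acid",    "decrease",                "increase_then_decrease",
    "L-alanine",       "amino acid",    "decrease",                "decrease",
    "L-glutamate",     "amino acid",    "decrease",                "decrease",
    "L-proline",       "amino acid",    "flat",                    "decrease",
    "L-valine",        "amino acid",    "flat",                    "flat",
    "fumarate",        "organic acid",  "fluctuate",               "fluctuate",
    "pyruvate",        "organic acid",  "fluctuate",               "fluctuate",
    "2-oxoglutarate",  "organic acid",  "increase",                "increase"
  )
}

# noiseless base shapes over the five metabolomics timepoints
pattern_base <- function(pattern, timepoints) {
  n <- length(timepoints)
  shape <- switch(
    pattern,
    decrease = exp(-seq(0, 2, length.out = n)),
    increase = seq(0.15, 1, length.out = n),
    increase_then_decrease = c(0.3, 1, 0.6, 0.4, 0.25)[seq_len(n)],
    fluctuate = c(0.5, 1, 0.4, 0.9, 0.5)[seq_len(n)],
    flat = rep(1, n),
    stop(sprintf("unknown temporal pattern '%s'", pattern), call. = FALSE)
  )
  shape
}

#' Simulate an untargeted metabolite intensity table
#'
#' Deterministic base trajectories per pattern over the metabolomics
#' timepoints, multiplied by a per-metabolite intensity scale and
#' median-preserving log-normal technical-replicate noise. The
#' increase-then-decrease pattern peaks at the second timepoint (12 h on the
#' default grid).
#'
#' @param config A [simulation_config()] (seed).
#' @param profiles Tibble mapping metabolites to per-treatment pattern
#'   labels, see [default_metabolite_profiles()].
#' @param timepoints Metabolomics sampling times in hours.
#' @param n_replicates Technical replicates per sample (default 5).
#' @param technical_cv CV of technical-replicate noise.
#' @return Tidy tibble: `metabolite`, `class`, `treatment`, `timepoint_h`,
#'   `replicate`, `intensity`, plus the noiseless `base_intensity`.
#' @export
#' @examples
#' cfg <- default_scenario(seed = 5)
#' m <- simulate_metabolite_matrix(cfg, n_replicates = 2)
#' head(m)
simulate_metabolite_matrix <- function(config,
                                       profiles = default_metabolite_profiles(),
                                       timepoints = c(0, 12, 24, 36, 48),
                                       n_replicates = 5L,
                                       technical_cv = 0.1) {
  stopifnot(inherits(config, "simulation_config"))
  treatments <- setdiff(names(profiles), c("metabolite", "class"))
  bad <- setdiff(unlist(profiles[treatments]), METABOLITE_PATTERNS)
  if (length(bad)) {
    stop(sprintf("unknown temporal pattern '%s'", bad[1]), call. = FALSE)
  }

  grid <- tidyr::expand_grid(
    metabolite = profiles$metabolite,
    treatment = treatments,
    timepoint_h = timepoints
  )
  scales <- with_seed_if(config$seed + 21L,
                         stats::setNames(stats::rlnorm(nrow(profiles), 11, 1),
                                         profiles$metabolite))
  base_of <- function(met, trt) {
    pat <- profiles[[trt]][match(met, profiles$metabolite)]
    pattern_base(pat, timepoints) * scales[[met]]
  }
  grid$base_intensity <- unlist(lapply(seq_len(nrow(profiles)), function(i) {
    unlist(lapply(treatments, function(trt) {
      base_of(profiles$metabolite[i], trt)
    }))
  }))

  out <- tidyr::expand_grid(grid, replicate = seq_len(n_replicates))
  out$intensity <- with_seed_if(config$seed + 22L,
                                apply_lognormal_noise(out$base_intensity,
                                                      technical_cv))
  out$class <- profiles$class[match(out$metabolite, profiles$metabolite)]
  dplyr::select(out, "metabolite", "class", "treatment", "timepoint_h",
                "replicate", "intensity", "base_intensity")
}

#' Simulate a complete incubation experiment
#'
#' Convenience wrapper running the germination-growth engine, the amplicon
#' count generator and the metabolite generator from one configuration.
#'
#' @param config A [simulation_config()].
#' @param trajectories Community trajectories; defaults to
#'   [default_community_trajectories()].
#' @param metabolite_profiles Metabolite pattern roster.
#' @return A `simulated_experiment` with all components filled.
#' @export
simulate_experiment <- function(config,
                                trajectories = default_community_trajectories(config),
                                metabolite_profiles = default_metabolite_profiles()) {
  exp <- simulate_germination_growth(config)
  exp$asv_table <- simulate_asv_counts(config, trajectories)
  exp$metabolites <- simulate_metabolite_matrix(config, metabolite_profiles)
  exp
}
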