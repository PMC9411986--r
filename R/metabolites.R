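#' Logarithmically normalized mean fractional abundance
#'
#' For each metabolite within a treatment: technical replicates are averaged
#' per timepoint, the means are expressed as fractions of that metabolite's
#' summed means across timepoints (so each metabolite-treatment row sums to
#' one before the log), and the fractions are log10-transformed after adding
#' a pseudo-fraction. This is the per-compound temporal shape used for
#' heatmap display, invariant to global rescaling of raw intensities. A
#' per-sample-total alternative is available via `by = "sample"`.
#'
#' @param data Tidy intensity table with columns `metabolite`, `treatment`,
#'   `timepoint_h`, `replicate`, `intensity`.
#' @param pseudo Pseudo-fraction added before the log (default 1e-6).
#' @param by `"timepoint"` (default; fractions across timepoints within
#'   metabolite) or `"sample"` (fractions of each sample's total).
#' @return Tibble: `metabolite`, `treatment`, `timepoint_h`,
#'   `mean_intensity`, `fraction`, `log_fraction`. Metabolites with all-zero
#'   intensities in a treatment are emitted with `NA` fractions and a
#'   warning.
#' @export
normalize_fractional <- function(data, pseudo = 1e-6,
                                 by = c("timepoint", "sample")) {
  by <- match.arg(by)
  assert_number(pseudo, "pseudo", 0, strict_lower = TRUE)
  stopifnot(all(c("metabolite", "treatment", "timepoint_h", "replicate",
                  "intensity") %in% names(data)))
  means <- data |>
    dplyr::group_by(.data$metabolite, .data$treatment, .data$timepoint_h) |>
    dplyr::summarise(mean_intensity = mean(.data$intensity),
                     .groups = "drop")
  if (by == "sample") {
    out <- means |>
      dplyr::group_by(.data$treatment, .data$timepoint_h) |>
      dplyr::mutate(total = sum(.data$mean_intensity)) |>
      dplyr::ungroup()
  } else {
    out <- means |>
      dplyr::group_by(.data$metabolite, .data$treatment) |>
      dplyr::mutate(total = sum(.data$mean_intensity)) |>
      dplyr::ungroup()
  }
  zero <- unique(out$metabolite[out$total == 0])
  if (length(zero)) {
    warning(sprintf("all-zero intensities for: %s",
                    paste(zero, collapse = ", ")), call. = FALSE)
  }
  out |>
    dplyr::mutate(
      fraction = ifelse(.data$total > 0,
                        .data$mean_intensity / .data$total, NA_real_),
      log_fraction = log10(.data$fraction + pseudo)
    ) |>
    dplyr::select(-"total")
}

#' Classify the temporal pattern of a normalized profile
#'
#' Consecutive differences are compared against a tolerance band of
#' `tolerance` times the profile's range; differences inside the band count
#' as no change. All effective decreases give `"decrease"`, all increases
#' `"increase"`, increases followed by decreases with a single sign change
#' `"increase_then_decrease"`, no effective change `"flat"`, anything else
#' `"fluctuate"`. The label is invariant to strictly monotone transforms of
#' the profile up to the band discretization.
#'
#' @param x Numeric profile ordered by time (>= 3 values).
#' @param tolerance Band half-width as a fraction of the range (default 0.1).
#' @return One of `"decrease"`, `"increase_then_decrease"`, `"increase"`,
#'   `"fluctuate"`, `"flat"`.
#' @export
#' @examples
#' classify_temporal_pattern(c(1, 5, 3, 2, 1.5))
classify_temporal_pattern <- function(x, tolerance = 0.1) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  rng <- diff(range(x))
  if (rng == 0) return("flat")
  band <- tolerance * rng
  d <- diff(x)
  s <- sign(d) * (abs(d) > band)
  s <- s[s != 0]
  if (!length(s)) return("flat")
  if (all(s > 0)) return("increase")
  if (all(s < 0)) return("decrease")
  flips <- sum(diff(s) != 0)
  if (flips == 1L && s[1] > 0) return("increase_then_decrease")
  "fluctuate"
}

#' Classify temporal patterns for every metabolite-treatment profile
#'
#' @param normalized Output of [normalize_fractional()] (or any tibble with
#'   `metabolite`, `treatment`, `timepoint_h` and a value column).
#' @param value Column to classify on (default `log_fraction`).
#' @param tolerance Passed to [classify_temporal_pattern()].
#' @return Tibble: `metabolite`, `treatment`, `pattern`.
#' @export
classify_temporal_patterns <- function(normalized, value = "log_fraction",
                                       tolerance = 0.1) {
  normalized |>
    dplyr::arrange(.data$timepoint_h) |>
    dplyr::group_by(.data$metabolite, .data$treatment) |>
    dplyr::summarise(
      pattern = if (anyNA(.data[[value]])) NA_character_ else
        classify_temporal_pattern(.data[[value]], tolerance),
      .groups = "drop"
    )
}

#' PERMANOVA clustering significance on metabolite profiles
#'
#' One-way permutational multivariate analysis of variance on Euclidean
#' distances: pseudo-F = ((SS_total - SS_within) / (k - 1)) /
#' (SS_within / (n - k)), with the p value computed from seeded label
#' permutations as `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param x Numeric matrix, samples in rows (e.g. log-normalized metabolite
#'   profiles), or a `dist` object.
#' @param groups Factor-like group labels, one per sample; at least two
#'   groups of at least two samples each.
#' @param n_perm Number of permutations (>= 99, default 999).
#' @param seed Integer seed for the permutations.
#' @return Tibble: `pseudo_F`, `p_value`, `n_perm`, `n_samples`, `n_groups`.
#' @export
#' @examples
#' m <- rbind(matrix(rnorm(20), 4), matrix(rnorm(20, 2), 4))
#' cluster_significance(m, rep(c("a", "b"), each = 4), n_perm = 99, seed = 1)
cluster_significance <- function(x, groups, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop("`n_perm` must be at least 99", call. = FALSE)
  d2 <- if (inherits(x, "dist")) as.matrix(x)^2 else
    as.matrix(stats::dist(x))^2
  n <- nrow(d2)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 samples", call. = FALSE)
  }
  k <- nlevels(droplevels(groups))
  ss_total <- sum(d2) / (2 * n)
  pseudo_f <- function(g) {
    ss_within <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- pseudo_f(groups)
  f_perm <- with_seed_if(seed, {
    vapply(seq_len(n_perm),
           function(i) pseudo_f(groups[sample.int(n)]), numeric(1))
  })
  tibble::tibble(
    pseudo_F = f_obs,
    p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
    n_perm = as.integer(n_perm),
    n_samples = n,
    n_groups = k
  )
}

#' Build a samples-by-metabolites matrix from a tidy intensity table
#'
#' Log10-transformed intensities (with pseudo-count) arranged for ordination
#' or [cluster_significance()]; one row per treatment x timepoint x
#' replicate sample.
#'
#' @param data Tidy intensity table as in [normalize_fractional()].
#' @param pseudo Pseudo-count added before log10.
#' @return List with `matrix` (samples x metabolites) and `meta` (tibble:
#'   `sample_id`, `treatment`, `timepoint_h`, `replicate`).
#' @export
metabolite_sample_matrix <- function(data, pseudo = 1) {
  wide <- data |>
    dplyr::mutate(sample_id = paste(.data$treatment, .data$timepoint_h,
                                    .data$replicate, sep = "_")) |>
    dplyr::select("sample_id", "treatment", "timepoint_h", "replicate",
                  "metabolite", "intensity") |>
    tidyr::pivot_wider(names_from = "metabolite",
                       values_from = "intensity")
  meta <- dplyr::select(wide, "sample_id", "treatment", "timepoint_h",
                        "replicate")
  m <- log10(as.matrix(dplyr::select(wide, -"sample_id", -"treatment",
                                     -"timepoint_h", -"replicate")) + pseudo)
  rownames(m) <- meta$sample_id
  list(matrix = m, meta = meta)
}
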