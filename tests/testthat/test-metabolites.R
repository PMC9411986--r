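tidy_profile <- function(values, metabolite = "m", treatment = "amended",
                         reps = 1) {
  tidyr::expand_grid(
    metabolite = metabolite, treatment = treatment,
    timepoint_h = c(0, 12, 24, 36, 48), replicate = seq_len(reps)
  ) |>
    dplyr::mutate(intensity = rep(values, each = reps))
}

test_that("fractional normalization reproduces worked examples", {
  even <- normalize_fractional(tidy_profile(rep(7, 5)))
  expect_equal(even$fraction, rep(0.2, 5))
  spike <- normalize_fractional(tidy_profile(c(0, 100, 0, 0, 0)))
  expect_equal(spike$fraction[spike$timepoint_h == 12], 1)
  expect_equal(sum(spike$fraction), 1)
  expect_warning(
    z <- normalize_fractional(tidy_profile(rep(0, 5))),
    "all-zero")
  expect_true(all(is.na(z$fraction)))
})

test_that("normalization is invariant to global rescaling", {
  withr::with_seed(51, {
    v <- runif(5, 1, 100)
    a <- normalize_fractional(tidy_profile(v))
    b <- normalize_fractional(tidy_profile(v * 1e3))
    expect_equal(a$fraction, b$fraction, tolerance = 1e-12)
    expect_equal(a$log_fraction, b$log_fraction, tolerance = 1e-12)
  })
})

test_that("argmax of a peaked profile survives normalization", {
  cfg <- default_scenario(noise_cv = 0, seed = 2)
  m <- simulate_metabolite_matrix(cfg, n_replicates = 1, technical_cv = 0)
  norm <- normalize_fractional(m)
  cit <- subset(norm, metabolite == "L-citrulline" & treatment == "amended")
  expect_equal(cit$timepoint_h[which.max(cit$log_fraction)], 12)
})

test_that("temporal patterns classify canonical shapes", {
  expect_equal(classify_temporal_pattern(c(10, 6, 4, 2, 1)), "decrease")
  expect_equal(classify_temporal_pattern(c(2, 10, 6, 4, 3)),
               "increase_then_decrease")
  expect_equal(classify_temporal_pattern(c(1, 2, 4, 8, 16)), "increase")
  expect_equal(classify_temporal_pattern(rep(3, 5)), "flat")
  expect_equal(classify_temporal_pattern(c(5, 1, 6, 2, 7)), "fluctuate")
  expect_error(classify_temporal_pattern(c(1, 2)), "3 timepoints")
})

test_that("pattern labels are invariant to strictly monotone transforms", {
  withr::with_seed(52, {
    profiles <- list(c(9, 5, 3, 2, 1), c(1, 8, 5, 3, 2), c(1, 2, 4, 7, 9))
    for (x in profiles) {
      base <- classify_temporal_pattern(log(x))
      expect_equal(classify_temporal_pattern(log(x) * 3 + 2), base)
      # rank-preserving but nonlinear
      expect_equal(classify_temporal_pattern(rank(x) * 2), base)
    }
  })
})

test_that("simulated patterns round-trip through the classifier", {
  cfg <- default_scenario(noise_cv = 0, seed = 4)
  m <- simulate_metabolite_matrix(cfg, n_replicates = 1, technical_cv = 0)
  norm <- normalize_fractional(m)
  pat <- classify_temporal_patterns(norm)
  prof <- default_metabolite_profiles()
  truth <- tidyr::pivot_longer(prof, c("amended", "unamended"),
                               names_to = "treatment",
                               values_to = "pattern_true")
  joined <- dplyr::inner_join(pat, truth,
                              by = c("metabolite", "treatment"))
  expect_true(all(joined$pattern == joined$pattern_true))
})

test_that("replicate geometric means track the base trajectory", {
  cfg <- default_scenario(noise_cv = 0, seed = 6)
  m <- simulate_metabolite_matrix(cfg, n_replicates = 5, technical_cv = 0.1)
  sdlog <- sqrt(log1p(0.1^2))
  stats <- m |>
    dplyr::group_by(metabolite, treatment, timepoint_h) |>
    dplyr::summarise(gm = exp(mean(log(intensity))),
                     base = base_intensity[1], .groups = "drop")
  # 2 SE of the log-mean, back on the intensity scale
  ratio_bound <- exp(2 * sdlog / sqrt(5))
  frac_ok <- mean(stats$gm / stats$base < ratio_bound &
                    stats$gm / stats$base > 1 / ratio_bound)
  expect_gt(frac_ok, 0.9)
})

test_that("unknown pattern labels are rejected", {
  prof <- default_metabolite_profiles()[1, ]
  prof$amended <- "oscillate"
  cfg <- default_scenario(seed = 1)
  expect_error(simulate_metabolite_matrix(cfg, prof), "oscillate")
})

test_that("PERMANOVA saturates for well-separated groups", {
  withr::with_seed(53, {
    m <- rbind(matrix(rnorm(100, 0, 0.2), 10), matrix(rnorm(100, 5, 0.2), 10))
    res <- cluster_significance(m, rep(c("a", "b"), each = 10),
                                n_perm = 199, seed = 9)
    expect_equal(res$p_value, 1 / 200)
    expect_gt(res$pseudo_F, 100)
  })
  expect_error(cluster_significance(matrix(rnorm(10), 5), c("a", "a", "a", "a", "b"),
                                    n_perm = 99, seed = 1),
               "at least 2 samples")
})

test_that("the permutation null is exchangeable under label permutation", {
  withr::with_seed(54, {
    m <- matrix(rnorm(60), 6)
    g <- rep(c("a", "b"), each = 3)
    r1 <- cluster_significance(m, g, n_perm = 199, seed = 7)
    # permuting the rows together with their labels leaves F unchanged
    perm <- sample(6)
    r2 <- cluster_significance(m[perm, ], g[perm], n_perm = 199, seed = 7)
    expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-12)
  })
})

test_that("pseudo-F matches vegan::adonis2 on a shared dataset", {
  skip_if_not_installed("vegan")
  withr::with_seed(55, {
    m <- rbind(matrix(rnorm(30), 3), matrix(rnorm(30, 1), 3))
    g <- rep(c("a", "b"), each = 3)
    ours <- cluster_significance(m, g, n_perm = 99, seed = 1)
    ref <- vegan::adonis2(dist(m) ~ g, permutations = 99)
    expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-9)
  })
})

test_that("PERMANOVA p-values are calibrated under the null", {
  withr::with_seed(56, {
    n_perm <- 199
    p <- vapply(1:1000, function(i) {
      m <- matrix(rnorm(32), 8)
      cluster_significance(m, rep(c("a", "b"), each = 4),
                           n_perm = n_perm, seed = i)$p_value
    }, numeric(1))
  })
  alpha <- 0.05
  rate <- mean(p <= alpha)
  # binomial 99% CI around the nominal level; attainable p-values are
  # multiples of 1/(n_perm+1), so alpha = 0.05 is exactly attainable
  ci <- 2.576 * sqrt(alpha * (1 - alpha) / 1000)
  expect_lt(abs(rate - alpha), ci + 1e-12)
})
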