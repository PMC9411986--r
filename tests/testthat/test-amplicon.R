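make_counts <- function(...) {
  m <- rbind(...)
  colnames(m) <- paste0("lib", seq_len(ncol(m)))
  rownames(m) <- paste0("ASV_", seq_len(nrow(m)))
  m
}

test_that("occurrence filter applies the 0.1% rule at read resolution", {
  counts <- make_counts(c(24), c(23), c(24000 - 47))
  tab <- tiny_asv_table(counts)
  pres <- filter_occurrence(tab)
  expect_true(pres["ASV_1", 1])   # 24 / 24,000 = exactly 0.1%
  expect_false(pres["ASV_2", 1])  # 23 / 24,000 < 0.1%
  zero <- make_counts(c(0, 0), c(50, 100))
  tab2 <- tiny_asv_table(zero)
  expect_true(all(!filter_occurrence(tab2)["ASV_1", ]))
})

test_that("zero-total libraries are rejected by name", {
  counts <- make_counts(c(5, 0), c(5, 0))
  expect_error(tiny_asv_table(counts), "lib2")
})

test_that("enrichment requires absence at t0 and >1% during incubation", {
  # rows: bloomer (0 at t0, 15% at 24 h), resident (5% then 40%),
  # nearly (0.05% t0, max 0.9%), filler
  counts <- make_counts(
    c(0, 1500, 100),
    c(500, 4000, 150),
    c(5, 60, 90),
    c(9495, 4440, 9660)
  )
  tab <- tiny_asv_table(counts, timepoints = c(0, 24, 48),
                        treatments = c("sediment_t0", "amended", "amended"))
  calls <- classify_enriched(tab)
  expect_true(calls$enriched[calls$asv_id == "ASV_1"])
  expect_false(calls$enriched[calls$asv_id == "ASV_2"]) # present before
  expect_false(calls$enriched[calls$asv_id == "ASV_3"]) # 0.009 <= 0.01
  expect_equal(calls$first_detection_h[calls$asv_id == "ASV_1"], 24)
  # missing t0 libraries are an error
  tab2 <- tiny_asv_table(counts, timepoints = c(12, 24, 48),
                         treatments = rep("amended", 3))
  expect_error(classify_enriched(tab2), "sediment_t0")
})

test_that("enrichment is monotone in its thresholds", {
  withr::with_seed(5, {
    counts <- matrix(rpois(60, 40), 6, 10)
    counts[2, ] <- c(0, rpois(9, 400))
    colnames(counts) <- paste0("lib", 1:10)
    rownames(counts) <- paste0("ASV_", 1:6)
    tab <- tiny_asv_table(counts, timepoints = c(0, seq(12, 108, 12)),
                          treatments = c("sediment_t0", rep("amended", 9)))
    base <- classify_enriched(tab, 0.001, 0.01)
    stricter <- classify_enriched(tab, 0.001, 0.05)
    expect_true(all(base$enriched | !stricter$enriched))
    looser_occ <- classify_enriched(tab, 0.0005, 0.01)
    expect_true(all(looser_occ$present_t0 | !base$present_t0))
  })
})

test_that("rarefaction hits the target depth exactly and is reproducible", {
  withr::with_seed(9, {
    counts <- matrix(rpois(50, 500), 10, 5)
    colnames(counts) <- paste0("lib", 1:5)
    rownames(counts) <- paste0("ASV_", 1:10)
  })
  tab <- tiny_asv_table(counts)
  r <- rarefy_counts(tab, 1000, seed = 3)
  expect_true(all(colSums(r$counts) == 1000))
  r2 <- rarefy_counts(tab, 1000, seed = 3)
  expect_identical(r$counts, r2$counts)
  # depth equal to the library total leaves counts unchanged
  tot <- colSums(tab$counts)
  expect_error(rarefy_counts(tab, max(tot) + 1), "lib")
  same <- rarefy_counts(tiny_asv_table(counts[, 1, drop = FALSE]),
                        tot[1], seed = 1)
  expect_identical(same$counts[, 1], tab$counts[, 1])
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- make_counts(c(30), c(50), c(20))
  tab <- tiny_asv_table(counts)
  depth <- 40
  draws <- vapply(1:10000, function(s) {
    rarefy_counts(tab, depth, seed = s)$counts[, 1]
  }, numeric(3))
  expected <- counts[, 1] * depth / sum(counts[, 1])
  # hypergeometric variance per ASV
  N <- sum(counts[, 1])
  v <- depth * (counts[, 1] / N) * (1 - counts[, 1] / N) *
    (N - depth) / (N - 1)
  se <- sqrt(v / 10000)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("multinomial library simulation matches its moments", {
  cfg <- simulation_config(
    populations = list(population_spec("p", n0 = 1, doubling_time_h = 1,
                                       cs_srr = 1)),
    time_grid = c(0, 3), noise_cv = 0, seed = 1, sequencing_depth = 200
  )
  shares <- matrix(c(0.5, 0.3, 0.2), 3, 1,
                   dimnames = list(paste0("ASV_", 1:3), "libA"))
  traj <- list(
    libraries = tibble::tibble(library_id = "libA", treatment = "amended",
                               timepoint_h = 12),
    shares = shares
  )
  counts <- vapply(1:10000, function(s) {
    cfg$seed <- s
    simulate_asv_counts(cfg, traj)$counts[, 1]
  }, numeric(3))
  p <- shares[, 1]
  se <- sqrt(200 * p * (1 - p) / 10000)
  expect_true(all(abs(rowMeans(counts) - 200 * p) < 3 * se))
})

test_that("a single-ASV community receives the full depth", {
  cfg <- simulation_config(
    populations = list(population_spec("p", n0 = 1, doubling_time_h = 1,
                                       cs_srr = 1)),
    time_grid = c(0, 3), noise_cv = 0, seed = 2, sequencing_depth = 5000
  )
  traj <- list(
    libraries = tibble::tibble(library_id = "only", treatment = "amended",
                               timepoint_h = 12),
    shares = matrix(1, 1, 1, dimnames = list("ASV_1", "only"))
  )
  tab <- simulate_asv_counts(cfg, traj)
  expect_equal(unname(tab$counts[1, 1]), 5000L)
  # mismatched labels and bad shares are errors
  bad <- traj
  colnames(bad$shares) <- "other"
  expect_error(simulate_asv_counts(cfg, bad), "library ids")
  bad2 <- traj
  bad2$shares[1, 1] <- 0.8
  expect_error(simulate_asv_counts(cfg, bad2), "sum to 1")
})

test_that("default scenario is a rare biosphere whose bloomers all enrich", {
  cfg <- default_scenario(noise_cv = 0, seed = 3)
  tab <- simulate_asv_counts(cfg, default_community_trajectories(cfg))
  roster <- default_bloomer_roster()
  rel <- relative_abundance(tab)
  # every bloomer below the occurrence cutoff at time zero
  expect_true(all(rel[roster$asv_id, "sediment_t0"] < 0.001))
  # at least one bloomer above 1% by 24 h
  expect_gt(max(rel[roster$asv_id, "amended_024h"]), 0.01)
  calls <- classify_enriched(tab)
  expect_setequal(calls$asv_id[calls$enriched], roster$asv_id)
})

test_that("class aggregation sums to one and mirrors the treatment contrast", {
  cfg <- default_scenario(noise_cv = 0, seed = 3)
  tab <- simulate_asv_counts(cfg, default_community_trajectories(cfg))
  agg <- aggregate_taxonomy(tab, "class")
  sums <- tapply(agg$fraction, agg$library_id, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  des <- subset(agg, taxon == "Desulfotomaculia" & timepoint_h >= 24)
  ratio <- mean(des$fraction[des$treatment == "amended"]) /
    mean(des$fraction[des$treatment == "unamended"])
  expect_gt(ratio, 4)
  expect_lt(ratio, 25)
  # single-class table collapses to fraction 1
  one <- tiny_asv_table(make_counts(c(10, 20), c(30, 40)))
  agg1 <- aggregate_taxonomy(one, "class")
  expect_true(all(agg1$fraction == 1))
  expect_true(all(agg1$taxon == "Clostridia"))
})
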