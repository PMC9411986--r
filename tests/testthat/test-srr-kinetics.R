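test_that("log-linear fitting recovers a known doubling time exactly", {
  t <- 9:23
  d <- data.frame(time_h = t, rate_nmol_cm3_d = 2^(t / 1.5))
  fit <- fit_exponential_phase(d, 9, 23)
  expect_equal(fit$doubling_time, 1.5, tolerance = 1e-9)
  expect_equal(fit$mu * fit$doubling_time, log(2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("constant rates give mu = 0 and an infinite, flagged doubling time", {
  d <- data.frame(time_h = 0:9, rate_nmol_cm3_d = rep(3, 10))
  fit <- fit_exponential_phase(d, 0, 9)
  expect_equal(fit$mu, 0)
  expect_identical(fit$doubling_time, Inf)
  expect_true(fit$no_growth)
  expect_error(estimate_population(fit), "no growth")
})

test_that("rescaling rates leaves mu unchanged and shifts the intercept", {
  t <- seq(2, 20, by = 2)
  d <- data.frame(time_h = t, rate_nmol_cm3_d = exp(0.3 * t + 1))
  f1 <- fit_exponential_phase(d, 2, 20)
  d2 <- transform(d, rate_nmol_cm3_d = 2 * rate_nmol_cm3_d)
  f2 <- fit_exponential_phase(d2, 2, 20)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept + log(2), tolerance = 1e-9)
})

test_that("doubling time times mu equals ln 2 for every fit", {
  withr::with_seed(11, {
    for (i in 1:20) {
      mu <- runif(1, 0.01, 1)
      t <- sort(sample(0:50, 8))
      d <- data.frame(time_h = t,
                      rate_nmol_cm3_d = exp(mu * t) * exp(rnorm(8, 0, 0.1)))
      fit <- fit_exponential_phase(d, min(t), max(t))
      if (is.finite(fit$doubling_time)) {
        expect_equal(fit$mu * fit$doubling_time, log(2), tolerance = 1e-12)
      }
    }
  })
})

test_that("non-positive rates inside a window are named in the error", {
  d <- data.frame(time_h = 0:5, rate_nmol_cm3_d = c(1, 2, 0, 8, 16, 32))
  expect_error(fit_exponential_phase(d, 0, 5), "t = 2")
})

test_that("duplicate measurements are averaged before fitting", {
  d <- data.frame(time_h = rep(0:5, 2),
                  rate_nmol_cm3_d = c(exp(0:5) * 1.25, exp(0:5) * 0.75),
                  replicate = rep(1:2, each = 6))
  fit <- fit_exponential_phase(d, 0, 5)
  expect_equal(fit$n_points, 6L)
  expect_equal(fit$mu, 1, tolerance = 1e-9)
})

test_that("csSRR model is the product of its factors and scales linearly", {
  m <- cs_srr_from_biovolume(1, 1, 1)
  expect_equal(m$cs_srr, 1)
  expect_equal(cs_srr_from_biovolume(2, 1, 1)$cs_srr, 2)
  expect_error(cs_srr_from_biovolume(-1, 1, 1))
  # N0 scales exactly as the inverse biovolume ratio
  d <- data.frame(time_h = 5:15, rate_nmol_cm3_d = exp(0.4 * (5:15)))
  fit <- fit_exponential_phase(d, 5, 15)
  n0_a <- estimate_population(fit, cs_srr_from_biovolume(1, 1, 10))$n0
  n0_b <- estimate_population(fit, cs_srr_from_biovolume(2.5, 1, 10))$n0
  expect_equal(n0_a / n0_b, 2.5, tolerance = 1e-12)
})

test_that("a constructed intercept inverts to the intended census", {
  cs <- 10
  d <- data.frame(time_h = 0:9,
                  rate_nmol_cm3_d = cs * 1e-6 * 100 * 2^(0:9))
  fit <- fit_exponential_phase(d, 0, 9)
  est <- estimate_population(fit, cs_srr_from_biovolume(1, 1, cs))
  expect_equal(est$n0, 100, tolerance = 1e-6)
})

test_that("simulate-fit-estimate round trip recovers the generator census", {
  cfg <- single_pop_config(n0 = 500, td = 2, cs = 10, noise_cv = 0)
  exp <- simulate_germination_growth(cfg)
  w <- detect_exponential_phases(exp$srr)
  expect_equal(nrow(w), 1L)
  fit <- fit_exponential_phase(exp$srr, w$t_start[1], w$t_end[1])
  est <- estimate_population(fit, cs_srr_from_biovolume(1, 1, 10))
  expect_equal(est$n0 / 500, 1, tolerance = 0.05)
  expect_equal(fit$doubling_time, 2, tolerance = 1e-6)
})

test_that("a pure exponential yields one window spanning all positive points", {
  d <- data.frame(time_h = seq(0, 20, 2), rate_nmol_cm3_d = exp(0.2 * seq(0, 20, 2)))
  w <- detect_exponential_phases(d)
  expect_equal(nrow(w), 1L)
  expect_equal(w$t_start, 0)
  expect_equal(w$t_end, 20)
})

test_that("constant and all-zero series yield no windows", {
  flat <- data.frame(time_h = 0:9, rate_nmol_cm3_d = rep(2, 10))
  expect_equal(nrow(detect_exponential_phases(flat)), 0L)
  zero <- data.frame(time_h = 0:9, rate_nmol_cm3_d = rep(0, 10))
  expect_equal(nrow(detect_exponential_phases(zero)), 0L)
  sparse <- data.frame(time_h = 0:5, rate_nmol_cm3_d = c(0, 0, 0, 1, 2, 0))
  expect_warning(w <- detect_exponential_phases(sparse), "min_points")
  expect_equal(nrow(w), 0L)
})

test_that("noiseless default scenario reproduces the configured phase windows", {
  cfg <- default_scenario(noise_cv = 0, seed = 1)
  exp <- simulate_germination_growth(cfg)
  srr <- subset(exp$srr, time_h <= 126)
  w <- detect_exponential_phases(srr)
  expect_equal(nrow(w), 2L)
  # early window opens at the configured onset and closes within one grid
  # step of the growth end
  expect_equal(w$t_start[1], 9)
  expect_lte(w$t_end[1], 24)
  # late window opens after the early population's decay, before 54 h
  expect_gte(w$t_start[2], 30)
  expect_lte(w$t_start[2], 54)
})

test_that("noisy replicates recover both doubling times and censuses", {
  res <- purrr::map_dfr(1:100, function(s) {
    cfg <- default_scenario(noise_cv = 0.05, seed = s)
    exp <- simulate_germination_growth(cfg)
    k <- analyze_srr(subset(exp$srr, time_h <= 126))
    expect_equal(nrow(k), 2L)
    tibble::tibble(td1 = k$doubling_time[1], td2 = k$doubling_time[2],
                   n01 = k$n0[1], n02 = k$n0[2])
  })
  expect_lt(median(abs(res$td1 - 1.5) / 1.5), 0.05)
  expect_lt(median(abs(res$td2 - 8) / 8), 0.1)
  expect_true(all(res$n01 > 160 / 1.5 & res$n01 < 160 * 1.5))
  expect_true(all(res$n02 > 4.5e4 / 1.5 & res$n02 < 4.5e4 * 1.5))
})

test_that("tidy and glance summarize fits and estimates", {
  d <- data.frame(time_h = 0:9, rate_nmol_cm3_d = exp(0.5 * (0:9)))
  fit <- fit_exponential_phase(d, 0, 9)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("mu", "doubling_time", "intercept"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_points, 10L)
  est <- generics::tidy(estimate_population(fit))
  expect_true(all(c("n0", "doubling_time", "cs_srr") %in% names(est)))
})
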