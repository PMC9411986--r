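test_that("monotone series yield single full-range phases", {
  conc <- data.frame(time_h = c(0, 10, 20, 30), analyte = "lactate",
                     mean_mM = c(4, 3, 1, 0.2))
  seg <- segment_phases(conc, "lactate")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$direction, "depletion")
  expect_equal(c(seg$t_start, seg$t_end), c(0, 30))

  flat <- data.frame(time_h = c(0, 10, 20, 30), analyte = "acetate",
                     mean_mM = c(1, 1.0004, 0.9998, 1.0001))
  seg2 <- segment_phases(flat, "acetate")
  expect_equal(seg2$direction, "stable")
  expect_equal(nrow(seg2), 1L)
  expect_error(segment_phases(conc, "butyrate"), "butyrate")
})

test_that("phase windows tile the time axis without gaps or overlaps", {
  withr::with_seed(41, {
    for (i in 1:10) {
      t <- sort(sample(0:200, 12))
      conc <- data.frame(time_h = t, analyte = "x",
                         mean_mM = abs(cumsum(rnorm(12))))
      seg <- segment_phases(conc, "x")
      expect_equal(seg$t_start[1], t[1])
      expect_equal(seg$t_end[nrow(seg)], t[12])
      if (nrow(seg) > 1) {
        expect_equal(seg$t_start[-1], seg$t_end[-nrow(seg)])
      }
    }
  })
})

test_that("succinate depletion and propionate accumulation coincide mid-incubation", {
  cfg <- default_scenario(noise_cv = 0, seed = 1)
  exp <- simulate_germination_growth(cfg)
  succ <- segment_phases(exp$concentrations, "succinate")
  prop <- segment_phases(exp$concentrations, "propionate")
  dep <- succ[succ$direction == "depletion", ]
  acc <- prop[prop$direction == "accumulation", ]
  expect_equal(nrow(dep), 1L)
  expect_equal(nrow(acc), 1L)
  # both windows overlap the 48-72 h interval
  expect_lt(dep$t_start, 72)
  expect_gt(dep$t_end, 48)
  expect_lt(acc$t_start, 72)
  expect_gt(acc$t_end, 48)
})

test_that("net change propagates uncertainty and is antisymmetric", {
  conc <- data.frame(time_h = c(0, 216), analyte = "sulfate",
                     mean_mM = c(15.6, 2.5), sd_mM = c(0.3, 0.1))
  nc <- net_change(conc, "sulfate", 0, 216)
  expect_equal(nc$delta_mM, -13.1)
  expect_equal(nc$sd_mM, sqrt(0.09 + 0.01), tolerance = 1e-12)
  rev <- net_change(conc, "sulfate", 216, 0)
  expect_equal(rev$delta_mM, -nc$delta_mM)
  expect_equal(rev$sd_mM, nc$sd_mM)
  same <- net_change(rbind(conc, conc), "sulfate", 0, 0)
  expect_equal(same$delta_mM, 0)
  expect_error(net_change(conc, "sulfate", 0, 100), "grid")
})

test_that("decarboxylation alone explains a 1:1 succinate-propionate swap", {
  bal <- stoichiometric_balance(c(succinate = -4, propionate = 4),
                                default_reaction_table())
  ext <- setNames(bal$extents$extent_mM, bal$extents$reaction)
  expect_equal(unname(ext["succinate_decarboxylation"]), 4, tolerance = 1e-9)
  expect_equal(sum(ext) - ext[["succinate_decarboxylation"]], 0,
               tolerance = 1e-9)
  expect_lt(bal$residual_norm, 1e-9)
  # all-zero deltas give all-zero extents
  bal0 <- stoichiometric_balance(c(succinate = 0, sulfate = 0),
                                 default_reaction_table())
  expect_true(all(bal0$extents$extent_mM == 0))
  # disjoint reactions are an error
  rx <- reaction_table(other = list(substrates = c(glucose = 1),
                                    products = c(), sulfate = 0))
  expect_error(stoichiometric_balance(c(sulfate = -1), rx), "no analytes")
})

test_that("extents are invariant to analyte ordering", {
  d1 <- c(succinate = -2, propionate = 1, butyrate = -1, sulfate = -0.8,
          acetate = 2.5)
  d2 <- d1[c(4, 2, 5, 1, 3)]
  b1 <- stoichiometric_balance(d1, default_reaction_table())
  b2 <- stoichiometric_balance(d2, default_reaction_table())
  expect_equal(b1$extents, b2$extents, tolerance = 1e-9)
  # fitted residual never exceeds the zero-extent residual
  expect_lte(b1$residual_norm, sqrt(sum(d1^2)) + 1e-12)
})

test_that("the audit closes the mass balance of the noiseless scenario", {
  cfg <- default_scenario(noise_cv = 0, seed = 1)
  exp <- simulate_germination_growth(cfg)
  conc <- exp$concentrations
  t_end <- max(conc$time_h)
  deltas <- vapply(unique(conc$analyte), function(a) {
    x <- conc[conc$analyte == a, ]
    x$true_mM[x$time_h == t_end] - x$true_mM[x$time_h == 0]
  }, numeric(1))
  bal <- stoichiometric_balance(deltas, default_reaction_table())
  expect_lt(bal$residual_norm, 1e-6)
  consumed <- -deltas[["sulfate"]]
  expect_equal(bal$sulfate_demand_mM, consumed, tolerance = 1e-6)
})
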