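test_that("MAD matches hand computations and resists outliers", {
  expect_equal(mad_value(c(5, 5, 5, 5)), 0)
  expect_equal(mad_value(c(1, 2, 3, 4, 5)), 1.4826)
  expect_equal(mad_value(c(1, 1, 1, 100)), 0)
  expect_equal(mad_value(c(1, 2, 3), constant = 1), 1)
  expect_error(mad_value(numeric(0)), "empty")
})

test_that("bootstrap MAD matches the exact resample enumeration", {
  expect_equal(bootstrap_mad(rep(3, 10), B = 50, seed = 1), 0)
  # length-3 input: all 27 equally likely resamples enumerable exactly
  x <- c(1, 2, 3)
  expect_equal(bootstrap_mad(x, B = 10000, seed = 42),
               boot_mad_enum_oracle(x), tolerance = 0.05)
  x2 <- c(2, 7, 11)
  expect_equal(bootstrap_mad(x2, B = 10000, seed = 13),
               boot_mad_enum_oracle(x2), tolerance = 0.1)
})

test_that("bootstrap MAD approaches the plug-in MAD for large samples", {
  set.seed(8)
  x <- rnorm(500, sd = 3)
  bm <- bootstrap_mad(x, B = 1000, seed = 5)
  expect_equal(bm, mad_value(x), tolerance = 0.1 * mad_value(x))
})

test_that("bootstrap MAD is deterministic and permutation-invariant", {
  set.seed(4)
  x <- rgamma(30, 2, 0.1)
  expect_identical(bootstrap_mad(x, B = 200, seed = 9),
                   bootstrap_mad(x, B = 200, seed = 9))
  expect_identical(bootstrap_mad(x, B = 200, seed = 9),
                   bootstrap_mad(sample(x), B = 200, seed = 9))
  expect_error(bootstrap_mad(1, B = 10), "at least 2")
})

test_that("the expected-MAD trend reproduces flat and linear signals", {
  cfg <- ev_config(B = 10)
  med <- exp(seq(log(20), log(2000), length.out = 200))
  flat <- rep(7, 200)
  expect_equal(fit_expected_mad(med, flat, cfg), flat, tolerance = 1e-6)
  lin <- 2 + 3 * log1p(med)
  expect_lt(max(abs(fit_expected_mad(med, lin, cfg) / lin - 1)), 0.01)
})

test_that("an offset gene's EV recovers the injected offset", {
  cfg <- ev_config(B = 10)
  med <- exp(seq(log(20), log(2000), length.out = 300))
  madv <- 1 + 0.5 * log1p(med)
  madv[150] <- madv[150] + 50
  pred <- fit_expected_mad(med, madv, cfg)
  ev <- madv - pred
  expect_equal(ev[150], 50, tolerance = 5)
})

test_that("adding a constant to all observed MADs leaves EV unchanged", {
  set.seed(6)
  med <- exp(runif(120, log(30), log(1000)))
  madv <- 1 + 0.4 * log1p(med) + rnorm(120, sd = 0.2)
  cfg <- ev_config(B = 10)
  ev1 <- madv - fit_expected_mad(med, madv, cfg)
  ev2 <- (madv + 100) - fit_expected_mad(med, madv + 100, cfg)
  expect_equal(ev1, ev2, tolerance = 1e-6)  # loess is a linear smoother
})

test_that("EV tables satisfy the arithmetic contract and are deterministic", {
  sim <- tiny_sim()
  sf <- compute_size_factors(sim$counts)
  cfg <- ev_config(B = 50, seed = 2)
  ev1 <- compute_ev(sim$counts, sim$metadata, sf, cfg = cfg)
  ev2 <- compute_ev(sim$counts, sim$metadata, sf, cfg = cfg)
  expect_identical(ev1, ev2)
  expect_equal(ev1$ev, ev1$mad_obs - ev1$mad_pred)
  expect_true(all(ev1$mad_obs >= 0))
  # one record per gene x group x dose
  expect_equal(nrow(ev1), nrow(sim$counts) * 3)
  expect_error(compute_ev(sim$counts, sim$metadata[1:3, ], sf, cfg = cfg),
               "fewer than 4")
})

test_that("loess removes the mean-variability trend from EV", {
  # trend-only data: raw MAD tracks expression, EV must not
  cfg <- sim_config(n_genes = 1000, samples_per_group = 40,
                    groups = c("N0", "N1"), doses = "0",
                    frac_hyper = 0, frac_hypo = 0, frac_bimodal = 0,
                    frac_de = 0, seed = 51)
  sim <- simulate_counts(cfg)
  sf <- compute_size_factors(sim$counts)
  ev <- compute_ev(sim$counts, sim$metadata, sf,
                   cfg = ev_config(B = 100, seed = 6))
  ev0 <- ev[ev$group == "N0", ]
  expect_gt(kendall_tau(ev0$mad_obs, ev0$median_expr), 0.5)
  expect_lt(abs(kendall_tau(ev0$ev, ev0$median_expr)), 0.12)
})
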