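test_that("the reference interval matches constructed median and MAD", {
  # standard-normal quantiles: median 0, plug-in MAD ~ 1
  ev_ref <- qnorm(seq(0.01, 0.99, length.out = 101))
  thr <- reference_interval(ev_ref, B = 2000, k = 3, seed = 7)
  expect_equal(thr$ref_median_ev, 0, tolerance = 1e-10)
  expect_equal(thr$lower, -3, tolerance = 0.3)
  expect_equal(thr$upper, 3, tolerance = 0.3)

  # degenerate: all values equal -> zero width, no crash
  thr0 <- reference_interval(rep(2, 20), B = 100, k = 3, seed = 1)
  expect_equal(thr0$lower, 2)
  expect_equal(thr0$upper, 2)
  expect_identical(classify_ev(c(1.9, 2, 2.1), thr0),
                   c("hypo", "non", "hyper"))

  # k = 0 collapses the interval onto the median
  thrk <- reference_interval(ev_ref, B = 100, k = 0, seed = 1)
  expect_equal(thrk$lower, thrk$upper)
  expect_error(reference_interval(1:5, B = 10), "at least 10")
})

test_that("classification follows the closed-interval convention", {
  thr <- list(ref_median_ev = 10, ref_mad_ev = 50, k = 3,
              lower = -140, upper = 160)
  expect_identical(classify_ev(c(200, -200, 10), thr),
                   c("hyper", "hypo", "non"))
  # boundary values are non-variable
  expect_identical(classify_ev(c(-140, 160), thr), c("non", "non"))
})

test_that("the reference group classifies itself mostly non-variable", {
  cfg <- sim_config(n_genes = 600, samples_per_group = 52,
                    groups = c("N0", "N1"), doses = "0",
                    mean_log_mu_range = c(log(100), log(1000)),
                    frac_hyper = 0, frac_hypo = 0, frac_bimodal = 0,
                    frac_de = 0, seed = 77)
  sim <- simulate_counts(cfg)
  sf <- compute_size_factors(sim$counts)
  ev <- compute_ev(sim$counts, sim$metadata, sf,
                   cfg = ev_config(B = 100, seed = 3))
  wh <- classify_whole(ev, "N0", B = 200, k = 3, seed = 3)
  ref <- wh$labels[wh$labels$group == "N0", ]
  expect_gte(mean(ref$label == "non"), 0.9)
})

test_that("cross-validation output satisfies its structural contracts", {
  sim <- tiny_sim()
  sf <- compute_size_factors(sim$counts)
  genes <- filter_bimodal(sim$counts, sf,
                          bimodality_config(seed = 2))$retained
  cl <- crossvalidate(sim$counts, sim$metadata, sf, genes,
                      cfg = ev_config(B = 40, seed = 4), R = 6, seed = 4)
  # one row per retained gene x group x dose; labels partition the genes
  expect_equal(nrow(cl), length(genes) * 3)
  expect_true(all(cl$label_whole %in% c("hypo", "non", "hyper")))
  expect_true(all(cl$successes >= 0 & cl$successes <= 6))
  # binomial tail equals its closed form for every observed success count
  oracle <- vapply(cl$successes, function(s) {
    sum(choose(6, s:6)) / 2^6
  }, numeric(1))
  expect_equal(cl$p_binomial, oracle)
  expect_true(all(cl$p_adjusted >= cl$p_binomial - 1e-12))
  # conservatism: confirmed hypo/hyper sets are subsets of whole-data sets
  expect_true(all(cl$label_confirmed[cl$label_whole == "non"] == "non"))
  for (lab in c("hypo", "hyper")) {
    expect_true(all(cl$gene_id[cl$label_confirmed == lab] %in%
                      cl$gene_id[cl$label_whole == lab]))
  }
  # determinism
  cl2 <- crossvalidate(sim$counts, sim$metadata, sf, genes,
                       cfg = ev_config(B = 40, seed = 4), R = 6, seed = 4)
  expect_identical(cl, cl2)
})

test_that("triplet-level splits keep matched donors together", {
  sim <- tiny_sim()
  md <- sim$metadata
  set.seed(1)
  halves <- exvar:::split_half(md, by_triplet = TRUE)
  for (h in halves) {
    trip <- unique(md$triplet_id[md$sample_id %in% h])
    # every triplet in a half contributes all of its samples to that half
    expect_true(all(md$sample_id[md$triplet_id %in% trip] %in% h))
  }
  expect_equal(sort(unlist(halves)), sort(md$sample_id))
})

test_that("widening the interval multiplier weakly shrinks hypo/hyper sets", {
  cfg <- sim_config(n_genes = 300, samples_per_group = 12, doses = "0",
                    seed = 15)
  sim <- simulate_counts(cfg)
  sf <- compute_size_factors(sim$counts)
  ev <- compute_ev(sim$counts, sim$metadata, sf,
                   cfg = ev_config(B = 60, seed = 2))
  n_extreme <- sapply(c(1, 3, 6), function(k) {
    wh <- classify_whole(ev, "N0", B = 200, k = k, seed = 2)
    sum(wh$labels$label != "non")
  })
  expect_true(all(diff(n_extreme) <= 0))
})
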