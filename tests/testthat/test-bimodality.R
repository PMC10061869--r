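test_that("bimodality index matches its closed form and is label-swap symmetric", {
  expect_equal(bimodality_index(0.5, 0, 2, 1, 1), 1)
  expect_equal(bimodality_index(0.5, 0, 2, 1, 1),
               bimodality_index(0.5, 2, 0, 1, 1))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95)
    m <- rnorm(2); s <- runif(2, 0.3, 2)
    expect_equal(bimodality_index(p, m[1], m[2], s[1], s[2]),
                 bimodality_index(1 - p, m[2], m[1], s[2], s[1]))
  }
  # vanishing mixing proportion kills the index regardless of separation
  expect_lt(bimodality_index(1e-8, 0, 10, 1, 1), 1e-3)
})

test_that("EM recovers a well-separated mixture and its index", {
  # truth: pi = 0.5, delta mu = 2, sigma = 1 -> bi = 1; shift the log-means
  # up so counts clear the censoring threshold (bi is shift-invariant)
  set.seed(11)
  comp <- rbinom(2000, 1, 0.5)
  y <- rnorm(2000, mean = ifelse(comp == 1, 7, 5), sd = 1)
  counts <- as.integer(round(exp(y)))
  fit <- fit_lognormal_mixture(counts, rep(1, 2000),
                               bimodality_config(seed = 8))
  expect_true(fit$eligible)
  expect_equal(fit$bi, 1, tolerance = 0.1)
  expect_equal(fit$mu2 - fit$mu1, 2, tolerance = 0.25)
  # the mixing proportion is weakly identified at 2-sigma separation
  expect_equal(fit$pi, 0.5, tolerance = 0.25)
})

test_that("EM agrees with an independent mixture implementation", {
  set.seed(21)
  y <- c(rnorm(400, 5, 0.4), rnorm(600, 6.8, 0.6))
  counts <- as.integer(round(exp(y)))
  fit <- fit_lognormal_mixture(counts, rep(1, 1000),
                               bimodality_config(seed = 4))
  suppressMessages(library(mclust))
  mc <- Mclust(log(counts), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(c(fit$mu1, fit$mu2)), sort(unname(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4 * abs(mc$loglik))
})

test_that("unimodal expression rarely reaches the exclusion threshold", {
  set.seed(19)
  n_over <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    counts <- as.integer(round(exp(rnorm(104, 5.5, 0.5))))
    fit <- fit_lognormal_mixture(counts, rep(1, 104),
                                 bimodality_config(seed = r))
    if (isTRUE(fit$bi >= 1.1)) n_over <- n_over + 1
  }
  expect_lte(n_over / reps, 0.05)
})

test_that("EM log-likelihood is monotone and traces are exposed", {
  sim <- tiny_sim()
  sf <- compute_size_factors(sim$counts)
  ids0 <- sim$metadata$sample_id
  for (g in c(1, 10, 25, 60)) {
    fit <- fit_lognormal_mixture(sim$counts[g, ids0], sf[ids0],
                                 bimodality_config(seed = 5),
                                 keep_trace = TRUE)
    if (!fit$eligible) next
    expect_true(fit$monotone)
    expect_true(all(diff(fit$trace) >= -1e-8 * (abs(fit$trace[-1]) + 1)))
  }
})

test_that("the index is invariant to rescaling all counts", {
  set.seed(30)
  counts <- as.integer(round(exp(rnorm(300, 5, 0.8))))
  cfg <- bimodality_config(seed = 12)
  f1 <- fit_lognormal_mixture(counts, rep(1, 300), cfg)
  f4 <- fit_lognormal_mixture(counts * 4L, rep(1, 300), cfg)
  # multiplying counts shifts the log values; bi depends only on shape
  expect_equal(f1$bi, f4$bi, tolerance = 0.05)
})

test_that("censoring rules flag ineligible genes and keep them", {
  cfg <- bimodality_config(seed = 2)
  # 30% of counts below eps = 10 -> ineligible, bi undefined
  counts <- c(rep(2L, 30), as.integer(round(exp(rnorm(70, 5, 0.5)))))
  fit <- fit_lognormal_mixture(counts, rep(1, 100), cfg)
  expect_false(fit$eligible)
  expect_true(is.na(fit$bi))
  expect_error(fit_lognormal_mixture(rep(1L, 50), rep(1, 50), cfg),
               "below eps")

  m <- rbind(g_low = counts,
             g_ok = as.integer(round(exp(rnorm(100, 5, 0.5)))))
  colnames(m) <- paste0("s", 1:100)
  fb <- filter_bimodal(m, rep(1, 100), cfg)
  expect_true("g_low" %in% fb$retained)  # cannot be assessed -> retained
})

test_that("exclusion uses a closed threshold and recovers injected bimodal genes", {
  # 54 pooled samples: reduced sample size, so the 1.3 cutoff convention
  cfg <- sim_config(n_genes = 200, samples_per_group = 18, doses = "0",
                    frac_hyper = 0, frac_hypo = 0, frac_de = 0,
                    frac_bimodal = 0.1, seed = 505)
  sim <- simulate_counts(cfg)
  sf <- compute_size_factors(sim$counts)
  fb <- filter_bimodal(sim$counts, sf,
                       bimodality_config(bi_threshold = 1.3, seed = 3))
  tr <- sim$truth[sim$truth$group == "N0", ]
  is_bim <- tr$true_bimodal[match(fb$fits$gene_id, tr$gene_id)]
  # injected bimodal genes are mostly excluded, unimodal mostly kept
  expect_gte(mean(fb$fits$excluded[is_bim]), 0.8)
  expect_lte(mean(fb$fits$excluded[!is_bim]), 0.05)
  expect_identical(fb$retained, fb$fits$gene_id[!fb$fits$excluded])

  # boundary semantics: a gene with bi equal to the threshold is excluded
  g <- which(is_bim & fb$fits$eligible)[1]
  bi_g <- fb$fits$bi[g]
  at <- filter_bimodal(sim$counts[g, , drop = FALSE], sf,
                       bimodality_config(bi_threshold = bi_g, seed = 3))
  above <- filter_bimodal(sim$counts[g, , drop = FALSE], sf,
                          bimodality_config(bi_threshold = bi_g + 1e-9,
                                            seed = 3))
  expect_equal(length(at$excluded), 1L)
  expect_equal(length(above$excluded), 0L)
})
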