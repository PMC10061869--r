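test_that("simulation is deterministic and labels match configured fractions", {
  cfg <- sim_config(n_genes = 100, samples_per_group = 6, doses = c("0", "2"),
                    seed = 9)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth, s2$truth)

  # per dose and non-reference group, class counts follow round(frac * n)
  tr <- s1$truth
  expect_equal(sum(tr$true_class == "hyper") / length(unique(tr$dose)),
               round(0.05 * 100))
  expect_equal(sum(tr$true_class == "hypo") / length(unique(tr$dose)),
               round(0.05 * 100))
  # bimodal genes are bimodal in every group and dose
  bim_genes <- unique(tr$gene_id[tr$true_bimodal])
  expect_equal(length(bim_genes), round(0.02 * 100))
  expect_true(all(tr$true_bimodal[tr$gene_id %in% bim_genes]))
  # reference group carries no injected dispersion effects
  expect_true(all(tr$true_class[tr$group == "N0"] == "non"))
  # exactly one class per gene x group x dose
  expect_equal(nrow(tr), 100 * 3 * 2)
  expect_false(anyNA(tr$true_class))
})

test_that("no injected effects means every gene is non-variable truth", {
  cfg <- sim_config(n_genes = 40, samples_per_group = 4, doses = "0",
                    frac_hyper = 0, frac_hypo = 0, seed = 2)
  tr <- simulate_counts(cfg)$truth
  expect_true(all(tr$true_class == "non"))
})

test_that("counts follow the negative-binomial moment identity", {
  # one expression level, no injected effects, unit size factors:
  # var = mu + phi * mu^2 with mu = 100, phi = 0.1 -> 1100
  cfg <- sim_config(n_genes = 10, samples_per_group = 1700,
                    groups = c("N0", "N1"), doses = "0",
                    mean_log_mu_range = c(log(100), log(100)),
                    dispersion_trend = c(a = 0, b = 0.1),
                    frac_hyper = 0, frac_hypo = 0, frac_bimodal = 0,
                    frac_de = 0, size_factor_range = c(1, 1), seed = 31)
  counts <- simulate_counts(cfg)$counts
  mns <- rowMeans(counts)
  vars <- apply(counts, 1, stats::var)
  # 3 standard errors: SE(mean) ~ sqrt(1100/n); SE(var) via NB kurtosis ~ 32
  expect_true(all(abs(mns - 100) < 3 * sqrt(1100 / 3400)))
  expect_true(all(abs(vars - 1100) < 3 * 35))
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(sim_config(frac_hyper = 1.2), "frac_hyper")
  expect_error(sim_config(frac_hyper = 0.5, frac_hypo = 0.4,
                          frac_bimodal = 0.2), "<= 1")
  expect_error(sim_config(effect_hyper = 0.5), "effect_hyper")
  expect_error(sim_config(size_factor_range = c(-1, 2)), "size_factor_range")
})

test_that("column subsampling is uniform, reproducible and bounded", {
  sim <- tiny_sim()
  n_all <- ncol(sim$counts)
  full <- subsample_columns(sim$counts, sim$metadata, n_all, seed = 1)
  expect_identical(full$counts, sim$counts)

  sub1 <- subsample_columns(sim$counts, sim$metadata, 10, seed = 7)
  sub2 <- subsample_columns(sim$counts, sim$metadata, 10, seed = 7)
  expect_identical(sub1$counts, sub2$counts)
  expect_equal(ncol(sub1$counts), 10)
  expect_identical(colnames(sub1$counts), sub1$metadata$sample_id)

  expect_error(subsample_columns(sim$counts, sim$metadata, n_all + 1),
               "exceeds")
})

test_that("simulator configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 30", "samples_per_group: 4", "seed: 3",
               "frac_bimodal: 0.1"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 30L)
  expect_equal(cfg$frac_bimodal, 0.1)
  writeLines(c("n_genes: 30", "not_a_field: 1"), path)
  expect_error(read_sim_config(path), "not_a_field")
})
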