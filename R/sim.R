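#' Configuration for the negative-binomial count simulator
#'
#' The simulator emulates the design this pipeline targets: three donor
#' groups (reference first), each donor irradiated at three doses, counts per
#' gene drawn from a negative binomial whose dispersion follows a decreasing
#' mean--dispersion trend `phi(mu) = a / mu + b`. A minority of genes carry
#' group-specific dispersion inflation (hyper-variable truth) or deflation
#' (hypo-variable truth), a minority are bimodally expressed in every group,
#' and a minority are differentially expressed between groups.
#'
#' @param n_genes Number of genes.
#' @param samples_per_group Donors per donor group (each measured at every
#'   dose); the study analogue is 52.
#' @param groups Ordered donor-group labels, reference group first.
#' @param doses Ordered dose labels (Gray).
#' @param mean_log_mu_range Interval for the baseline natural-log mean
#'   expression, sampled uniformly per gene.
#' @param dispersion_trend Coefficients `c(a, b)` of `phi(mu) = a/mu + b`.
#' @param frac_hyper,frac_hypo Fractions of genes whose dispersion is
#'   inflated/deflated in exactly one non-reference group.
#' @param effect_hyper,effect_hypo Multiplicative dispersion factors (> 1);
#'   hyper genes get `phi * effect_hyper`, hypo genes `phi / effect_hypo` in
#'   their affected group.
#' @param frac_bimodal Fraction of genes expressed as an equal-weight
#'   two-component mixture in every group and dose.
#' @param bimodal_shift Natural-log separation between the two component
#'   means of bimodal genes.
#' @param frac_de Fraction of genes with a between-group mean shift.
#' @param effect_de Natural-log fold change applied to DE genes in one
#'   non-reference group.
#' @param size_factor_range Interval for the per-sample scaling factor,
#'   sampled uniformly.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       samples_per_group = 52L,
                       groups = c("N0", "N1", "N2+"),
                       doses = c("0", "0.05", "2"),
                       mean_log_mu_range = c(log(20), log(2000)),
                       dispersion_trend = c(a = 3, b = 0.05),
                       frac_hyper = 0.05,
                       frac_hypo = 0.05,
                       effect_hyper = 8,
                       effect_hypo = 8,
                       frac_bimodal = 0.02,
                       bimodal_shift = 1.5,
                       frac_de = 0.02,
                       effect_de = 1,
                       size_factor_range = c(0.7, 1.4),
                       seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(samples_per_group, "samples_per_group", lower = 1)
  if (length(groups) < 2L || anyDuplicated(groups)) {
    stop_field("groups", "need >= 2 unique group labels (reference first)")
  }
  if (length(doses) < 1L || anyDuplicated(doses)) {
    stop_field("doses", "need >= 1 unique dose labels")
  }
  if (length(mean_log_mu_range) != 2L || diff(mean_log_mu_range) < 0) {
    stop_field("mean_log_mu_range", "must be an increasing interval")
  }
  if (length(dispersion_trend) != 2L || any(dispersion_trend < 0) ||
      dispersion_trend[2] <= 0) {
    stop_field("dispersion_trend", "need a >= 0 and b > 0")
  }
  for (f in c("frac_hyper", "frac_hypo", "frac_bimodal", "frac_de")) {
    assert_scalar_number(get(f), f, lower = 0, upper = 1)
  }
  if (frac_hyper + frac_hypo + frac_bimodal + frac_de > 1) {
    stop_field("frac_hyper", paste(
      "frac_hyper + frac_hypo + frac_bimodal + frac_de must be <= 1"))
  }
  assert_scalar_number(effect_hyper, "effect_hyper", lower = 1, strict_lower = TRUE)
  assert_scalar_number(effect_hypo, "effect_hypo", lower = 1, strict_lower = TRUE)
  assert_scalar_number(bimodal_shift, "bimodal_shift", lower = 0)
  assert_scalar_number(effect_de, "effect_de", lower = 0)
  if (length(size_factor_range) != 2L || any(size_factor_range <= 0) ||
      diff(size_factor_range) < 0) {
    stop_field("size_factor_range", "must be a strictly positive interval")
  }
  assert_scalar_number(seed, "seed", lower = 0)

  structure(list(
    n_genes = as.integer(n_genes),
    samples_per_group = as.integer(samples_per_group),
    groups = as.character(groups),
    doses = as.character(doses),
    mean_log_mu_range = as.numeric(mean_log_mu_range),
    dispersion_trend = stats::setNames(as.numeric(dispersion_trend), c("a", "b")),
    frac_hyper = frac_hyper, frac_hypo = frac_hypo,
    effect_hyper = effect_hyper, effect_hypo = effect_hypo,
    frac_bimodal = frac_bimodal, bimodal_shift = bimodal_shift,
    frac_de = frac_de, effect_de = effect_de,
    size_factor_range = as.numeric(size_factor_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulator configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match [sim_config()] arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, cfg)
}

# Per-gene theoretical log-scale SD of NB(mu, phi) counts via the
# log-normal moment match: Var(log X) ~ log(1 + phi + 1/mu).
nb_log_sd <- function(mu, phi) sqrt(log(1 + phi + 1 / mu))

#' Simulate a count matrix with known variability ground truth
#'
#' Counts for gene g in sample j are drawn from a negative binomial with mean
#' `s_j * mu_g * (group/dose effects)` and dispersion `phi_g * (class
#' effect)`, where `phi_g = a / mu_g + b`. Hyper- and hypo-variable truth is
#' injected by inflating/deflating the dispersion in exactly one non-reference
#' group per affected gene; bimodal genes draw each donor from one of two
#' components whose log-means differ by `bimodal_shift` in every group and
#' dose; DE genes get a mean shift in one non-reference group.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `counts` (integer matrix, genes x samples),
#'   `metadata` (data.frame: sample_id, donor_group, dose, triplet_id, sex,
#'   smoking_pack_years, alcohol_per_day), `truth` (data.frame per gene x
#'   group x dose: true_class, true_bimodal, true_de, true_dispersion,
#'   true_bi), `size_factors` (the injected per-sample factors) and `config`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, samples_per_group = 6,
#'                                   doses = "0", seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  ng <- config$n_genes
  spg <- config$samples_per_group
  groups <- config$groups
  doses <- config$doses
  ref <- groups[1]
  alt_groups <- groups[-1]

  gene_ids <- sprintf("gene%05d", seq_len(ng))

  # --- gene-level assignments -------------------------------------------
  n_hyper <- round(config$frac_hyper * ng)
  n_hypo <- round(config$frac_hypo * ng)
  n_bimod <- round(config$frac_bimodal * ng)
  n_de <- round(config$frac_de * ng)
  assign <- with_seed(derive_seed(config$seed, "sim", "assign"), {
    perm <- sample.int(ng)
    list(
      hyper = perm[seq_len(n_hyper)],
      hypo = perm[n_hyper + seq_len(n_hypo)],
      bimodal = perm[n_hyper + n_hypo + seq_len(n_bimod)],
      de = perm[n_hyper + n_hypo + n_bimod + seq_len(n_de)],
      hyper_group = sample(alt_groups, n_hyper, replace = TRUE),
      hypo_group = sample(alt_groups, n_hypo, replace = TRUE),
      de_group = sample(alt_groups, n_de, replace = TRUE)
    )
  })

  log_mu <- with_seed(derive_seed(config$seed, "sim", "mu"), {
    stats::runif(ng, config$mean_log_mu_range[1], config$mean_log_mu_range[2])
  })
  mu <- exp(log_mu)
  a <- config$dispersion_trend[["a"]]
  b <- config$dispersion_trend[["b"]]
  phi <- a / mu + b

  # --- samples -----------------------------------------------------------
  meta <- expand.grid(donor = seq_len(spg), donor_group = groups, dose = doses,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$triplet_id <- sprintf("T%03d", meta$donor)
  meta$sample_id <- sprintf("%s_d%02d_%sGy", gsub("+", "p", meta$donor_group,
                                                  fixed = TRUE),
                            meta$donor, meta$dose)
  covars <- with_seed(derive_seed(config$seed, "sim", "covariates"), {
    sex <- sample(c("female", "male"), spg, replace = TRUE)
    packs <- ifelse(stats::runif(spg * length(groups)) < 0.7, 0,
                    round(stats::runif(spg * length(groups), 0, 25), 1))
    alco <- sample(0:3, spg * length(groups), replace = TRUE,
                   prob = c(0.5, 0.3, 0.1, 0.1))
    list(sex = sex, packs = packs, alco = alco)
  })
  # sex is matched within triplet; smoking/alcohol vary per donor
  meta$sex <- covars$sex[meta$donor]
  donor_key <- match(paste(meta$donor_group, meta$donor),
                     unique(paste(meta$donor_group, meta$donor)))
  meta$smoking_pack_years <- covars$packs[donor_key]
  meta$alcohol_per_day <- covars$alco[donor_key]
  ns <- nrow(meta)

  sf <- with_seed(derive_seed(config$seed, "sim", "sizefactors"), {
    stats::runif(ns, config$size_factor_range[1], config$size_factor_range[2])
  })
  names(sf) <- meta$sample_id

  # bimodal component membership is a per-donor trait, shared across doses
  comp <- with_seed(derive_seed(config$seed, "sim", "bimodal"), {
    matrix(stats::runif(n_bimod * spg * length(groups)) < 0.5,
           nrow = max(n_bimod, 0L))
  })

  # --- per gene x group effect lookup tables ----------------------------
  disp_mult <- matrix(1, ng, length(groups), dimnames = list(NULL, groups))
  mean_lfc <- matrix(0, ng, length(groups), dimnames = list(NULL, groups))
  if (n_hyper) disp_mult[cbind(assign$hyper, match(assign$hyper_group, groups))] <-
    config$effect_hyper
  if (n_hypo) disp_mult[cbind(assign$hypo, match(assign$hypo_group, groups))] <-
    1 / config$effect_hypo
  if (n_de) mean_lfc[cbind(assign$de, match(assign$de_group, groups))] <-
    config$effect_de
  is_bimodal <- logical(ng)
  is_bimodal[assign$bimodal] <- TRUE

  grp_idx <- match(meta$donor_group, groups)
  donor_idx <- donor_key  # 1..spg*length(groups), consistent across doses

  counts <- with_seed(derive_seed(config$seed, "sim", "counts"), {
    m <- matrix(0L, ng, ns, dimnames = list(gene_ids, meta$sample_id))
    half <- config$bimodal_shift / 2
    for (g in seq_len(ng)) {
      mu_j <- sf * mu[g] * exp(mean_lfc[g, grp_idx])
      if (is_bimodal[g]) {
        bi_row <- match(g, assign$bimodal)
        up <- comp[bi_row, donor_idx]
        mu_j <- mu_j * exp(ifelse(up, half, -half))
      }
      phi_j <- phi[g] * disp_mult[g, grp_idx]
      m[g, ] <- stats::rnbinom(ns, mu = mu_j, size = 1 / phi_j)
    }
    m
  })

  # --- truth table -------------------------------------------------------
  truth <- expand.grid(gene_id = gene_ids, group = groups, dose = doses,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g_of <- match(truth$gene_id, gene_ids)
  mult <- disp_mult[cbind(g_of, match(truth$group, groups))]
  truth$true_class <- ifelse(mult > 1, "hyper", ifelse(mult < 1, "hypo", "non"))
  truth$true_bimodal <- is_bimodal[g_of]
  truth$true_de <- mean_lfc[cbind(g_of, match(truth$group, groups))] != 0
  truth$true_dispersion <- phi[g_of] * mult
  # theoretical bimodality index of injected bimodal genes: equal weights,
  # component log-SDs from the NB log-scale moment match
  truth$true_bi <- NA_real_
  if (n_bimod) {
    bim <- truth$true_bimodal
    gb <- g_of[bim]
    s1 <- nb_log_sd(mu[gb] * exp(-config$bimodal_shift / 2), truth$true_dispersion[bim])
    s2 <- nb_log_sd(mu[gb] * exp(config$bimodal_shift / 2), truth$true_dispersion[bim])
    truth$true_bi[bim] <- bimodality_index(0.5, 0, config$bimodal_shift,
                                           s1, s2)
  }

  meta <- meta[, c("sample_id", "donor_group", "dose", "triplet_id", "sex",
                   "smoking_pack_years", "alcohol_per_day")]
  list(counts = counts, metadata = meta, truth = truth,
       size_factors = sf, config = config)
}

#' Subsample columns of a count matrix
#'
#' Draws `n` samples uniformly without replacement, keeping the metadata rows
#' consistent; input column order is preserved among the kept samples.
#'
#' @param counts Genes x samples count matrix.
#' @param metadata Sample metadata with a `sample_id` column.
#' @param n Number of samples to keep.
#' @param seed Integer seed.
#' @return List with subsetted `counts` and `metadata`.
#' @export
subsample_columns <- function(counts, metadata, n, seed = 1L) {
  if (n > ncol(counts)) {
    stop(sprintf("n = %d exceeds the %d available samples", n, ncol(counts)),
         call. = FALSE)
  }
  keep <- with_seed(derive_seed(seed, "subsample"),
                    sort(sample.int(ncol(counts), n)))
  ids <- colnames(counts)[keep]
  list(counts = counts[, keep, drop = FALSE],
       metadata = metadata[match(ids, metadata$sample_id), , drop = FALSE])
}
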