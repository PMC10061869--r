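#' Configuration for the bimodality filter
#'
#' Genes whose pooled expression across donor groups is bimodal are removed
#' per dose before any variability computation. Counts below `eps` are
#' treated as left-censored and dropped from the mixture fit; a gene whose
#' dropped fraction exceeds `zero_percent_thr` is flagged ineligible (its
#' bimodality cannot be assessed) and retained.
#'
#' @param bi_threshold Exclusion threshold on the bimodality index; genes
#'   with `bi >= bi_threshold` are removed. The convention is 1.1 for
#'   full-size data and 1.3 for reduced sample sizes (stratified runs).
#' @param zero_percent_thr Maximum tolerated fraction of counts below `eps`.
#' @param eps Count threshold below which observations are censored.
#' @param log_base Base of the log transform (natural log by default).
#' @param max_em_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` or `max_em_iter` iterations.
#' @param n_starts Number of EM starts: a 2-means split of the log values
#'   plus `n_starts - 1` random perturbations.
#' @param min_obs Minimum usable observations for a fit.
#' @param seed Integer seed for the random restarts.
#' @return A list of class `bimodality_config`.
#' @export
bimodality_config <- function(bi_threshold = 1.1, zero_percent_thr = 0.2,
                              eps = 10, log_base = exp(1),
                              max_em_iter = 500L, tol = 1e-8,
                              n_starts = 5L, min_obs = 6L, seed = 1L) {
  assert_scalar_number(bi_threshold, "bi_threshold", lower = 0, strict_lower = TRUE)
  assert_scalar_number(zero_percent_thr, "zero_percent_thr", lower = 0, upper = 1)
  assert_scalar_number(eps, "eps", lower = 0, strict_lower = TRUE)
  assert_scalar_number(max_em_iter, "max_em_iter", lower = 1)
  assert_scalar_number(tol, "tol", lower = 0, strict_lower = TRUE)
  assert_scalar_number(n_starts, "n_starts", lower = 1)
  structure(list(bi_threshold = bi_threshold,
                 zero_percent_thr = zero_percent_thr, eps = eps,
                 log_base = log_base, max_em_iter = as.integer(max_em_iter),
                 tol = tol, n_starts = as.integer(n_starts),
                 min_obs = as.integer(min_obs), seed = as.integer(seed)),
            class = "bimodality_config")
}

#' Bimodality index of a two-component mixture
#'
#' `sqrt(pi (1 - pi)) |mu1 - mu2| / sigma_pooled` with
#' `sigma_pooled = sqrt(pi sigma1^2 + (1 - pi) sigma2^2)`. Under equal
#' component SDs this reduces to the classical bimodality index; it is
#' invariant to swapping the component labels.
#'
#' @param pi Mixing proportion of component 1.
#' @param mu1,mu2 Component means (log scale).
#' @param sigma1,sigma2 Component SDs (log scale, > 0).
#' @return Non-negative bimodality index.
#' @examples
#' bimodality_index(0.5, 0, 2, 1, 1)  # = 1
#' @export
bimodality_index <- function(pi, mu1, mu2, sigma1, sigma2) {
  sigma_pooled <- sqrt(pi * sigma1^2 + (1 - pi) * sigma2^2)
  sqrt(pi * (1 - pi)) * abs(mu1 - mu2) / sigma_pooled
}

# one EM run from a given start; y is the vector of log expression values
em_two_normal <- function(y, start, max_iter, tol, keep_trace = FALSE) {
  p <- start$pi
  m1 <- start$mu1; m2 <- start$mu2
  s1 <- start$sigma1; s2 <- start$sigma2
  sd_floor <- max(stats::sd(y), 1e-6) * 1e-3
  ll_old <- -Inf
  trace <- if (keep_trace) numeric(0) else NULL
  converged <- FALSE
  min_step <- Inf  # most negative log-likelihood increment seen
  for (it in seq_len(max_iter)) {
    l1 <- log(p) + stats::dnorm(y, m1, s1, log = TRUE)
    l2 <- log1p(-p) + stats::dnorm(y, m2, s2, log = TRUE)
    mx <- pmax(l1, l2)
    ll <- sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
    if (keep_trace) trace <- c(trace, ll)
    if (is.finite(ll_old)) min_step <- min(min_step, ll - ll_old)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    r <- 1 / (1 + exp(l2 - l1))  # responsibility of component 1
    w1 <- sum(r); w2 <- length(y) - w1
    if (w1 < 1e-10 || w2 < 1e-10) break  # component died; keep last params
    p <- w1 / length(y)
    m1 <- sum(r * y) / w1
    m2 <- sum((1 - r) * y) / w2
    s1 <- max(sqrt(sum(r * (y - m1)^2) / w1), sd_floor)
    s2 <- max(sqrt(sum((1 - r) * (y - m2)^2) / w2), sd_floor)
  }
  list(pi = p, mu1 = m1, mu2 = m2, sigma1 = s1, sigma2 = s2,
       loglik = ll_old, converged = converged,
       monotone = !is.finite(min_step) || min_step >= -1e-8 * (abs(ll_old) + 1),
       trace = trace)
}

#' Fit a two-component log-normal mixture to one gene's counts
#'
#' Counts are normalized by the size factors, log-transformed, and fitted
#' with a two-component normal mixture by EM (best of `n_starts` restarts;
#' ties broken by mixing proportion closest to 1/2). Counts below `cfg$eps`
#' are censored out of the fit; when their fraction exceeds
#' `cfg$zero_percent_thr` the gene is reported ineligible with `bi = NA`.
#' Components are ordered so `mu1 <= mu2`.
#'
#' @param gene_counts Non-negative integer counts for one gene.
#' @param size_factors Per-sample positive factors.
#' @param cfg A [bimodality_config()].
#' @param keep_trace Keep the per-iteration log-likelihood trace of the best
#'   start (for monotonicity checks).
#' @return A list of class `mixture_fit`: `pi`, `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `loglik`, `bi`, `converged`, `eligible`, `n_used`,
#'   `frac_below_eps`, and optionally `trace`.
#' @export
fit_lognormal_mixture <- function(gene_counts, size_factors,
                                  cfg = bimodality_config(),
                                  keep_trace = FALSE) {
  stopifnot(length(gene_counts) == length(size_factors))
  frac_low <- mean(gene_counts < cfg$eps)
  keep <- gene_counts >= cfg$eps
  if (!any(keep)) {
    stop("all counts below eps; the mixture cannot be fitted", call. = FALSE)
  }
  out <- list(pi = NA_real_, mu1 = NA_real_, mu2 = NA_real_,
              sigma1 = NA_real_, sigma2 = NA_real_, loglik = NA_real_,
              bi = NA_real_, converged = FALSE, eligible = FALSE,
              monotone = NA, n_used = sum(keep), frac_below_eps = frac_low)
  class(out) <- "mixture_fit"
  if (frac_low > cfg$zero_percent_thr || sum(keep) < cfg$min_obs) {
    return(out)
  }
  y <- log(gene_counts[keep] / size_factors[keep], base = cfg$log_base)

  starts <- with_seed(derive_seed(cfg$seed, "bimodality", "starts"), {
    sy <- stats::sd(y)
    if (!is.finite(sy) || sy < 1e-12) sy <- 1e-6
    if (diff(range(y)) > 1e-12) {  # 2-means split of the log values
      km <- stats::kmeans(y, centers = range(y), iter.max = 50)
      base <- list(pi = mean(km$cluster == which.min(km$centers)),
                   mu1 = min(km$centers), mu2 = max(km$centers),
                   sigma1 = sy, sigma2 = sy)
    } else {
      base <- list(pi = 0.5, mu1 = y[1], mu2 = y[1] + 1e-6,
                   sigma1 = sy, sigma2 = sy)
    }
    base$pi <- min(max(base$pi, 0.05), 0.95)
    rand <- replicate(cfg$n_starts - 1L, simplify = FALSE, {
      ctr <- sort(sample(y, 2))
      list(pi = stats::runif(1, 0.2, 0.8), mu1 = ctr[1], mu2 = ctr[2],
           sigma1 = sy * stats::runif(1, 0.5, 1.5),
           sigma2 = sy * stats::runif(1, 0.5, 1.5))
    })
    c(list(base), rand)
  })

  fits <- lapply(starts, em_two_normal, y = y, max_iter = cfg$max_em_iter,
                 tol = cfg$tol, keep_trace = keep_trace)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- which(ll >= max(ll, na.rm = TRUE) - 1e-10)
  if (length(best) > 1L) {  # tie break: pi closest to 1/2
    bal <- vapply(fits[best], function(f) abs(f$pi - 0.5), numeric(1))
    best <- best[which.min(bal)]
  } else {
    best <- best[1]
  }
  fit <- fits[[best]]
  if (fit$mu1 > fit$mu2) {  # canonical order: mu1 <= mu2
    fit[c("mu1", "mu2")] <- fit[c("mu2", "mu1")]
    fit[c("sigma1", "sigma2")] <- fit[c("sigma2", "sigma1")]
    fit$pi <- 1 - fit$pi
  }
  out[c("pi", "mu1", "mu2", "sigma1", "sigma2", "loglik", "converged")] <-
    fit[c("pi", "mu1", "mu2", "sigma1", "sigma2", "loglik", "converged")]
  out$monotone <- all(vapply(fits, `[[`, logical(1), "monotone"))
  out$eligible <- TRUE
  out$bi <- bimodality_index(fit$pi, fit$mu1, fit$mu2, fit$sigma1, fit$sigma2)
  if (keep_trace) out$trace <- fit$trace
  out
}

#' Filter bimodally expressed genes
#'
#' Fits the mixture to every gene of a matrix (one dose, all donor groups
#' pooled) and excludes genes whose bimodality index reaches the threshold.
#' Ineligible genes (too many censored counts) are retained, since their
#' bimodality cannot be assessed.
#'
#' @param counts Genes x samples count matrix restricted to one dose.
#' @param size_factors Per-sample factors for those samples.
#' @param cfg A [bimodality_config()].
#' @return A list: `retained` and `excluded` gene id vectors (input order
#'   preserved) and `fits`, a data.frame with one row per gene (gene_id, pi,
#'   mu1, mu2, sigma1, sigma2, bi, eligible, excluded).
#' @export
filter_bimodal <- function(counts, size_factors, cfg = bimodality_config()) {
  if (nrow(counts) == 0L) stop("empty count matrix", call. = FALSE)
  fits <- lapply(seq_len(nrow(counts)), function(g) {
    f <- fit_lognormal_mixture(counts[g, ], size_factors, cfg)
    data.frame(gene_id = rownames(counts)[g], pi = f$pi, mu1 = f$mu1,
               mu2 = f$mu2, sigma1 = f$sigma1, sigma2 = f$sigma2, bi = f$bi,
               eligible = f$eligible, monotone = f$monotone,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  fits$excluded <- fits$eligible & !is.na(fits$bi) & fits$bi >= cfg$bi_threshold
  list(retained = fits$gene_id[!fits$excluded],
       excluded = fits$gene_id[fits$excluded],
       fits = fits)
}
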