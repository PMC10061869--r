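#' Configuration for the expression-variability computation
#'
#' @param B Bootstrap iterations for the observed MAD.
#' @param mad_constant Normal-consistency scale constant for the MAD.
#' @param loess_span,loess_degree Span (in (0, 1]) and local polynomial
#'   degree (1 or 2) of the loess fit of observed MAD on log1p median
#'   expression.
#' @param per_stratum_loess Fit the loess within each donor group x dose
#'   stratum (default) or once, pooled across strata.
#' @param seed Integer seed; per-gene bootstrap streams derive from it
#'   together with the gene id, group and dose.
#' @return A list of class `ev_config`.
#' @export
ev_config <- function(B = 1000L, mad_constant = 1.4826, loess_span = 0.75,
                      loess_degree = 2L, per_stratum_loess = TRUE,
                      seed = 1L) {
  assert_scalar_number(B, "B", lower = 1)
  assert_scalar_number(mad_constant, "mad_constant", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(loess_span, "loess_span", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (!loess_degree %in% c(1L, 2L)) {
    stop_field("loess_degree", "must be 1 or 2")
  }
  structure(list(B = as.integer(B), mad_constant = mad_constant,
                 loess_span = loess_span,
                 loess_degree = as.integer(loess_degree),
                 per_stratum_loess = isTRUE(per_stratum_loess),
                 seed = as.integer(seed)),
            class = "ev_config")
}

#' Median absolute deviation
#'
#' `constant * median(|x - median(x)|)`; the default constant 1.4826 makes
#' the estimator consistent for the SD under normality.
#'
#' @param x Numeric values (non-empty).
#' @param constant Scale constant.
#' @return Non-negative scalar.
#' @examples
#' mad_value(c(1, 2, 3, 4, 5))  # 1.4826
#' @export
mad_value <- function(x, constant = 1.4826) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  stats::mad(x, constant = constant)
}

#' Bootstrapped median absolute deviation
#'
#' The median over `B` bootstrap resamples (size n, with replacement) of the
#' resample MAD. The input is sorted before resampling, so the estimate is
#' invariant to permutations of an exchangeable sample.
#'
#' @param x Numeric values, `length(x) >= 2`.
#' @param B Number of bootstrap resamples.
#' @param constant MAD scale constant.
#' @param seed Integer seed.
#' @return Non-negative scalar, deterministic given `seed`.
#' @examples
#' bootstrap_mad(c(1, 2, 3), B = 100, seed = 1)
#' @export
bootstrap_mad <- function(x, B = 1000L, constant = 1.4826, seed = 1L) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  with_seed(seed, cpp_bootstrap_mad(sort(x), as.integer(B), constant))
}

#' Loess fit of expected MAD against expression magnitude
#'
#' Regresses observed MAD on `log1p(median_expr)` with a local polynomial
#' (loess) fit and evaluates it at each gene, giving the MAD a gene of that
#' expression level is expected to have under the common mean--variability
#' trend. Predictions outside the fitted predictor range are extended
#' linearly from the boundary.
#'
#' @param median_expr Per-gene median normalized expression.
#' @param mad_obs Per-gene observed MAD.
#' @param cfg An [ev_config()].
#' @param newdata Optional predictor values at which to evaluate (defaults to
#'   `median_expr`).
#' @return Numeric vector of predicted MADs.
#' @export
fit_expected_mad <- function(median_expr, mad_obs, cfg = ev_config(),
                             newdata = median_expr) {
  if (length(median_expr) < 10L) {
    stop("need at least 10 genes to fit the expected-MAD trend",
         call. = FALSE)
  }
  if (!all(is.finite(median_expr)) || !all(is.finite(mad_obs))) {
    stop("non-finite inputs to the loess fit", call. = FALSE)
  }
  x <- log1p(median_expr)
  fit <- stats::loess(mad_obs ~ x, span = cfg$loess_span,
                      degree = cfg$loess_degree,
                      data = data.frame(x = x, mad_obs = mad_obs),
                      control = stats::loess.control(surface = "direct"))
  xr <- range(x)
  xn <- log1p(newdata)
  pred <- stats::predict(fit, data.frame(x = pmin(pmax(xn, xr[1]), xr[2])))
  # linear extension beyond the fitted range from the boundary slope
  out_lo <- xn < xr[1]
  out_hi <- xn > xr[2]
  if (any(out_lo) || any(out_hi)) {
    h <- diff(xr) * 1e-3
    if (any(out_lo)) {
      f0 <- stats::predict(fit, data.frame(x = c(xr[1], xr[1] + h)))
      pred[out_lo] <- f0[1] + (xn[out_lo] - xr[1]) * (f0[2] - f0[1]) / h
    }
    if (any(out_hi)) {
      f1 <- stats::predict(fit, data.frame(x = c(xr[2] - h, xr[2])))
      pred[out_hi] <- f1[2] + (xn[out_hi] - xr[2]) * (f1[2] - f1[1]) / h
    }
  }
  unname(pred)
}

#' Per-gene expression variability by donor group and dose
#'
#' For each donor group x dose stratum independently: normalized expression
#' per gene, its median, the bootstrapped observed MAD, the loess-predicted
#' expected MAD at that gene's median expression, and their difference
#' `ev = mad_obs - mad_pred`. All quantities are in normalized-count units.
#'
#' @param counts Genes x samples count matrix.
#' @param metadata Sample metadata (`sample_id`, `donor_group`, `dose`).
#' @param size_factors Per-sample factors named by sample id.
#' @param genes Gene ids to evaluate; either a character vector (used for
#'   every dose) or a named list of per-dose gene id vectors, typically the
#'   retained genes after bimodality filtering.
#' @param cfg An [ev_config()].
#' @return data.frame: gene_id, group, dose, median_expr, mad_obs, mad_pred,
#'   ev; one row per gene x group x dose.
#' @export
compute_ev <- function(counts, metadata, size_factors,
                       genes = rownames(counts), cfg = ev_config()) {
  size_factors <- align_size_factors(size_factors, counts)
  genes_by_dose <- if (is.list(genes)) genes else {
    stats::setNames(rep(list(genes), length(unique(metadata$dose))),
                    unique(metadata$dose))
  }
  res <- list()
  for (dose in unique(metadata$dose)) {
    gd <- genes_by_dose[[dose]]
    if (is.null(gd)) stop("no gene list for dose ", dose, call. = FALSE)
    for (group in unique(metadata$donor_group)) {
      ids <- metadata$sample_id[metadata$donor_group == group &
                                  metadata$dose == dose]
      if (length(ids) < 4L) {
        stop(sprintf("stratum %s / %s Gy has fewer than 4 samples",
                     group, dose), call. = FALSE)
      }
      res[[paste(group, dose)]] <-
        ev_stratum(counts[gd, ids, drop = FALSE], size_factors[ids],
                   group, dose, cfg)
    }
  }
  out <- do.call(rbind, res)
  if (!cfg$per_stratum_loess) {  # one pooled trend across strata
    out$mad_pred <- fit_expected_mad(out$median_expr, out$mad_obs, cfg)
    out$ev <- out$mad_obs - out$mad_pred
  }
  rownames(out) <- NULL
  out
}

# EV table for one stratum (already subset to its samples and genes)
ev_stratum <- function(counts, size_factors, group, dose, cfg) {
  norm <- normalize_counts(counts, size_factors)
  med <- apply(norm, 1, stats::median)
  gene_ids <- rownames(counts)
  mad_obs <- vapply(seq_along(gene_ids), function(g) {
    bootstrap_mad(norm[g, ], B = cfg$B, constant = cfg$mad_constant,
                  seed = derive_seed(cfg$seed, "ev", gene_ids[g], group, dose))
  }, numeric(1))
  df <- data.frame(gene_id = gene_ids, group = group, dose = dose,
                   median_expr = unname(med), mad_obs = mad_obs,
                   mad_pred = NA_real_, ev = NA_real_,
                   stringsAsFactors = FALSE)
  df$mad_pred <- fit_expected_mad(df$median_expr, df$mad_obs, cfg)
  df$ev <- df$mad_obs - df$mad_pred
  df
}
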