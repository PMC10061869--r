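#' Competing variability metrics per gene and stratum
#'
#' Computes, per gene within each donor group x dose stratum: mean, sample SD
#' (n - 1), median, plug-in MAD, the coefficient of variation `cv = SD /
#' mean` and the standardized MAD `d = MAD / median`. Undefined ratios (zero
#' mean or median) are flagged as `NA`, not raised.
#'
#' @param counts Genes x samples count matrix.
#' @param metadata Sample metadata.
#' @param size_factors Per-sample factors.
#' @param genes Gene ids (character vector, or per-dose named list as from
#'   bimodality filtering).
#' @param mad_constant MAD scale constant.
#' @param ev_table Optional [compute_ev()] output to merge an `ev` column in.
#' @return data.frame: gene_id, group, dose, mean_expr, sd_expr, median_expr,
#'   mad_expr, cv, d (and ev if supplied).
#' @export
variability_metrics <- function(counts, metadata, size_factors,
                                genes = rownames(counts),
                                mad_constant = 1.4826, ev_table = NULL) {
  size_factors <- align_size_factors(size_factors, counts)
  genes_by_dose <- if (is.list(genes)) genes else {
    stats::setNames(rep(list(genes), length(unique(metadata$dose))),
                    unique(metadata$dose))
  }
  res <- list()
  for (dose in unique(metadata$dose)) {
    gd <- genes_by_dose[[dose]]
    for (group in unique(metadata$donor_group)) {
      ids <- metadata$sample_id[metadata$donor_group == group &
                                  metadata$dose == dose]
      if (length(ids) == 0L) next
      norm <- normalize_counts(counts[gd, ids, drop = FALSE],
                               size_factors[ids])
      mn <- rowMeans(norm)
      sdv <- apply(norm, 1, stats::sd)
      med <- apply(norm, 1, stats::median)
      madv <- apply(norm, 1, stats::mad, constant = mad_constant)
      res[[paste(group, dose)]] <- data.frame(
        gene_id = gd, group = group, dose = dose,
        mean_expr = unname(mn), sd_expr = unname(sdv),
        median_expr = unname(med), mad_expr = unname(madv),
        cv = ifelse(mn == 0, NA_real_, sdv / mn),
        d = ifelse(med == 0, NA_real_, madv / med),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(ev_table)) {
    key <- paste(out$gene_id, out$group, out$dose)
    out$ev <- ev_table$ev[match(key, paste(ev_table$gene_id, ev_table$group,
                                           ev_table$dose))]
  }
  out
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation; count-derived medians tie frequently,
#' so the tie-corrected form is used throughout.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Tau-b in `[-1, 1]`, or `NA` when either input is constant.
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2))  # 1/3
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(x, y, method = "kendall")
}

#' Association of variability metrics with expression magnitude
#'
#' Kendall tau-b of each metric against the median expression, per donor
#' group x dose and pooled across groups per dose (`group = "pooled"`).
#'
#' @param metric_table Output of [variability_metrics()] (with `ev` merged
#'   in when available).
#' @param metrics Metric column names to correlate.
#' @return data.frame: metric, dose, group, tau.
#' @export
metric_vs_expression <- function(metric_table,
                                 metrics = intersect(c("cv", "d", "ev"),
                                                     colnames(metric_table))) {
  rows <- list()
  for (dose in unique(metric_table$dose)) {
    sub_d <- metric_table[metric_table$dose == dose, , drop = FALSE]
    for (m in metrics) {
      for (group in c(unique(sub_d$group), "pooled")) {
        sub <- if (group == "pooled") sub_d else {
          sub_d[sub_d$group == group, , drop = FALSE]
        }
        if (nrow(sub) < 10L) next
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, dose = dose, group = group,
          tau = kendall_tau(sub[[m]], sub$median_expr),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Exclusive set intersections of variability classifications
#'
#' Builds, for one label (hypo or hyper), the gene sets per donor group x
#' dose holding genes with that confirmed label, then decomposes their union
#' into exclusive intersection cells (each gene counted in exactly one cell,
#' the one matching its full membership pattern) -- the decomposition an
#' UpSet plot displays.
#'
#' @param classifications A [crossvalidate()] result (or any data.frame with
#'   gene_id, group, dose and a label column).
#' @param label `"hypo"` or `"hyper"`.
#' @param label_col Column holding the labels (defaults to the confirmed
#'   labels).
#' @return data.frame with one row per non-empty exclusive cell: one logical
#'   membership column per set (named `group|dose`), `n_genes` and comma-
#'   joined `gene_ids`. The union size is attached as attribute `n_union`.
#' @export
exclusive_intersections <- function(classifications, label = c("hyper", "hypo"),
                                    label_col = "label_confirmed") {
  label <- match.arg(label)
  cl <- classifications
  sets <- lapply(split(cl$gene_id[cl[[label_col]] == label],
                       paste(cl$group[cl[[label_col]] == label],
                             cl$dose[cl[[label_col]] == label], sep = "|")),
                 unique)
  set_names <- sort(unique(paste(cl$group, cl$dose, sep = "|")))
  sets <- stats::setNames(lapply(set_names, function(s) sets[[s]] %||%
                                   character(0)), set_names)
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 0L) {
    membership <- matrix(logical(0), 0, length(sets),
                         dimnames = list(NULL, set_names))
  }
  if (is.null(dim(membership))) {
    membership <- matrix(membership, nrow = length(universe),
                         dimnames = list(NULL, set_names))
  }
  pattern <- apply(membership, 1, paste, collapse = "")
  rows <- lapply(unique(pattern), function(p) {
    in_cell <- pattern == p
    cbind(as.data.frame(membership[which(in_cell)[1], , drop = FALSE]),
          data.frame(n_genes = sum(in_cell),
                     gene_ids = paste(universe[in_cell], collapse = ","),
                     stringsAsFactors = FALSE))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    cbind(as.data.frame(matrix(logical(0), 0, length(sets),
                               dimnames = list(NULL, set_names))),
          data.frame(n_genes = integer(0), gene_ids = character(0)))
  }
  rownames(out) <- NULL
  out <- out[order(-out$n_genes), , drop = FALSE]
  attr(out, "n_union") <- length(universe)
  out
}
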