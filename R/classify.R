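#' Reference-group classification interval
#'
#' The hypo/non/hyper interval is `median(ev_ref) +/- k * MAD_EV`, where
#' `MAD_EV` is the bootstrapped MAD of the reference group's EV values
#' (median of `B` bootstrap iterations).
#'
#' @param ev_ref EV values of the reference donor group (>= 10 values).
#' @param B Bootstrap iterations.
#' @param constant MAD scale constant.
#' @param k Interval half-width multiplier.
#' @param seed Integer seed.
#' @return A list of class `classification_thresholds`: `ref_median_ev`,
#'   `ref_mad_ev`, `k`, `lower`, `upper`.
#' @export
reference_interval <- function(ev_ref, B = 1000L, constant = 1.4826, k = 3,
                               seed = 1L) {
  if (length(ev_ref) < 10L) {
    stop("need at least 10 reference EV values", call. = FALSE)
  }
  med <- stats::median(ev_ref)
  madv <- bootstrap_mad(ev_ref, B = B, constant = constant,
                        seed = derive_seed(seed, "refint"))
  structure(list(ref_median_ev = med, ref_mad_ev = madv, k = k,
                 lower = med - k * madv, upper = med + k * madv),
            class = "classification_thresholds")
}

#' Classify EV values against a reference interval
#'
#' Below the interval is hypo-variable, above is hyper-variable, inside or
#' exactly on a boundary is non-variable (closed interval, conservative).
#'
#' @param ev Numeric EV values.
#' @param thresholds A [reference_interval()] result.
#' @return Character vector in `c("hypo", "non", "hyper")`.
#' @export
classify_ev <- function(ev, thresholds) {
  ifelse(ev < thresholds$lower, "hypo",
         ifelse(ev > thresholds$upper, "hyper", "non"))
}

#' Whole-data hypo/non/hyper classification
#'
#' For each dose, the interval is anchored in the reference group's EV values
#' at that dose; all donor groups are then classified against it.
#'
#' @param ev_table Output of [compute_ev()].
#' @param reference_group Donor group whose EVs define the interval.
#' @param B,constant,k,seed Passed to [reference_interval()].
#' @return A list: `labels` (ev_table plus a `label` column) and
#'   `thresholds` (per-dose list).
#' @export
classify_whole <- function(ev_table, reference_group = "N0", B = 1000L,
                           constant = 1.4826, k = 3, seed = 1L) {
  if (!reference_group %in% ev_table$group) {
    stop("reference group ", reference_group, " absent from EV table",
         call. = FALSE)
  }
  ev_table$label <- NA_character_
  thresholds <- list()
  for (dose in unique(ev_table$dose)) {
    in_dose <- ev_table$dose == dose
    thr <- reference_interval(
      ev_table$ev[in_dose & ev_table$group == reference_group],
      B = B, constant = constant, k = k,
      seed = derive_seed(seed, "classify", dose))
    thresholds[[dose]] <- thr
    ev_table$label[in_dose] <- classify_ev(ev_table$ev[in_dose], thr)
  }
  list(labels = ev_table, thresholds = thresholds)
}

# split donors (or triplets) into two halves; returns list of 2 sample-id sets
split_half <- function(metadata, by_triplet = TRUE) {
  if (by_triplet) {
    units <- unique(metadata$triplet_id)
    perm <- sample(units)
    h1 <- perm[seq_len(floor(length(units) / 2))]
    in1 <- metadata$triplet_id %in% h1
    list(metadata$sample_id[in1], metadata$sample_id[!in1])
  } else {
    ids1 <- unlist(lapply(split(metadata$sample_id,
                                list(metadata$donor_group, metadata$dose),
                                drop = TRUE), function(ids) {
      sample(ids, floor(length(ids) / 2))
    }), use.names = FALSE)
    list(ids1, setdiff(metadata$sample_id, ids1))
  }
}

#' Split-half cross-validation of variability classifications
#'
#' Each donor group is split uniformly at random in half `R` times; the
#' complete EV and classification pipeline (reference interval re-estimated
#' from the reference group's half) is rerun on each half. A repeat counts as
#' a success for a gene when both halves reproduce the whole-data label. The
#' per-gene success count is tested against a fair coin (one-sided binomial,
#' alternative p > 1/2), p-values are Benjamini-Hochberg adjusted within each
#' donor group x dose, and unconfirmed hypo/hyper labels are reset to
#' non-variable. The bimodality filter is not re-run inside splits: the gene
#' universe per dose stays fixed.
#'
#' @param counts Genes x samples count matrix.
#' @param metadata Sample metadata.
#' @param size_factors Per-sample factors (from the full data).
#' @param genes Per-dose retained gene ids (named list) or a character
#'   vector.
#' @param cfg An [ev_config()].
#' @param reference_group Reference donor group label.
#' @param R Number of split-half repeats.
#' @param k Interval multiplier.
#' @param alpha FDR level for confirmation.
#' @param split_by_triplet Keep matched triplets together in a half (the
#'   three donors of a triplet land in the same half across groups);
#'   otherwise split each group x dose stratum independently.
#' @param seed Integer seed.
#' @param whole Optional precomputed [classify_whole()] result on the full
#'   data (computed if missing).
#' @return data.frame: gene_id, group, dose, label_whole, successes,
#'   p_binomial, p_adjusted, confirmed, label_confirmed.
#' @export
crossvalidate <- function(counts, metadata, size_factors,
                          genes = rownames(counts), cfg = ev_config(),
                          reference_group = "N0", R = 10L, k = 3,
                          alpha = 0.05, split_by_triplet = TRUE, seed = 1L,
                          whole = NULL) {
  size_factors <- align_size_factors(size_factors, counts)
  strata_n <- table(metadata$donor_group, metadata$dose)
  if (any(strata_n < 8L)) {
    stop("every donor group x dose stratum needs >= 8 samples to split",
         call. = FALSE)
  }
  if (is.null(whole)) {
    ev_whole <- compute_ev(counts, metadata, size_factors, genes, cfg)
    whole <- classify_whole(ev_whole, reference_group, B = cfg$B,
                            constant = cfg$mad_constant, k = k,
                            seed = cfg$seed)
  }
  res <- whole$labels[, c("gene_id", "group", "dose")]
  res$label_whole <- whole$labels$label
  res$successes <- 0L

  for (r in seq_len(R)) {
    halves <- with_seed(derive_seed(seed, "cv", "split", r),
                        split_half(metadata, by_triplet = split_by_triplet))
    labels_half <- lapply(seq_along(halves), function(h) {
      md <- metadata[metadata$sample_id %in% halves[[h]], , drop = FALSE]
      cfg_h <- cfg
      cfg_h$seed <- derive_seed(seed, "cv", "ev", r, h)
      ev_h <- compute_ev(counts[, md$sample_id, drop = FALSE], md,
                         size_factors, genes, cfg_h)
      classify_whole(ev_h, reference_group, B = cfg$B,
                     constant = cfg$mad_constant, k = k,
                     seed = derive_seed(seed, "cv", "thr", r, h))$labels
    })
    key <- function(df) paste(df$gene_id, df$group, df$dose)
    l1 <- labels_half[[1]]$label[match(key(res), key(labels_half[[1]]))]
    l2 <- labels_half[[2]]$label[match(key(res), key(labels_half[[2]]))]
    ok <- !is.na(l1) & !is.na(l2) & l1 == res$label_whole &
      l2 == res$label_whole
    res$successes <- res$successes + as.integer(ok)
  }

  res$p_binomial <- stats::pbinom(res$successes - 1L, R, 0.5,
                                  lower.tail = FALSE)
  res$p_adjusted <- NA_real_
  for (s in split(seq_len(nrow(res)), list(res$group, res$dose), drop = TRUE)) {
    res$p_adjusted[s] <- stats::p.adjust(res$p_binomial[s], method = "BH")
  }
  res$confirmed <- res$p_adjusted < alpha
  res$label_confirmed <- ifelse(res$confirmed, res$label_whole, "non")
  res
}
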