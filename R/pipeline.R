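#' Pipeline configuration
#'
#' Bundles every tunable of the variability pipeline. `bi_threshold = NULL`
#' selects the convention automatically: 1.1 on full data, 1.3 when the
#' metadata carries a `stratified` attribute set by [apply_strata()]
#' (reduced sample sizes need the higher cutoff).
#'
#' @param reference_group Donor group anchoring the classification interval.
#' @param bi_threshold Bimodality-index exclusion threshold, or `NULL` for
#'   automatic selection.
#' @param zero_percent_thr,eps Censoring rule of the bimodality fit.
#' @param B Bootstrap iterations (observed MAD and interval MAD).
#' @param R Cross-validation repeats.
#' @param k Interval half-width multiplier.
#' @param alpha FDR level (confirmation and enrichment).
#' @param mad_constant MAD scale constant.
#' @param loess_span,loess_degree Loess tuning.
#' @param split_by_triplet Split halves at matched-triplet level.
#' @param n_starts EM restarts per mixture fit.
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_group = "N0", bi_threshold = NULL,
                            zero_percent_thr = 0.2, eps = 10, B = 1000L,
                            R = 10L, k = 3, alpha = 0.05,
                            mad_constant = 1.4826, loess_span = 0.75,
                            loess_degree = 2L, split_by_triplet = TRUE,
                            n_starts = 5L, seed = 1L) {
  structure(list(reference_group = reference_group,
                 bi_threshold = bi_threshold,
                 zero_percent_thr = zero_percent_thr, eps = eps,
                 B = as.integer(B), R = as.integer(R), k = k, alpha = alpha,
                 mad_constant = mad_constant, loess_span = loess_span,
                 loess_degree = as.integer(loess_degree),
                 split_by_triplet = isTRUE(split_by_triplet),
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Stratify or filter samples before a pipeline run
#'
#' Sex stratification keeps one sex; lifestyle filters act at matched-triplet
#' level: a triplet is dropped entirely when any of its members smoked more
#' than `max_pack_years` pack years or drinks more than `max_alcohol`
#' alcoholic beverages per day. The returned metadata carries attribute
#' `stratified = TRUE` so the pipeline applies the higher bimodality-index
#' cutoff for reduced sample sizes.
#'
#' @param metadata Sample metadata.
#' @param sex Keep only this sex (`"female"`/`"male"`), or `NULL`.
#' @param max_pack_years Triplet-level smoking exclusion threshold, or
#'   `NULL`.
#' @param max_alcohol Triplet-level alcohol exclusion threshold, or `NULL`.
#' @param min_samples Minimum samples any donor group x dose stratum must
#'   keep; violated strata abort before the pipeline starts.
#' @return Filtered metadata (attribute `stratified` set when any filter was
#'   active).
#' @export
apply_strata <- function(metadata, sex = NULL, max_pack_years = NULL,
                         max_alcohol = NULL, min_samples = 8L) {
  md <- metadata
  any_filter <- FALSE
  if (!is.null(max_pack_years)) {
    if (!"smoking_pack_years" %in% colnames(md)) {
      stop("unknown column: smoking_pack_years", call. = FALSE)
    }
    bad <- unique(md$triplet_id[md$smoking_pack_years > max_pack_years])
    md <- md[!md$triplet_id %in% bad, , drop = FALSE]
    any_filter <- TRUE
  }
  if (!is.null(max_alcohol)) {
    if (!"alcohol_per_day" %in% colnames(md)) {
      stop("unknown column: alcohol_per_day", call. = FALSE)
    }
    bad <- unique(md$triplet_id[md$alcohol_per_day > max_alcohol])
    md <- md[!md$triplet_id %in% bad, , drop = FALSE]
    any_filter <- TRUE
  }
  if (!is.null(sex)) {
    if (!"sex" %in% colnames(md)) stop("unknown column: sex", call. = FALSE)
    md <- md[md$sex == sex, , drop = FALSE]
    any_filter <- TRUE
  }
  if (any_filter) {
    n <- table(md$donor_group, md$dose)
    if (nrow(md) == 0L || any(n < min_samples)) {
      stop(sprintf(
        "stratification leaves a donor group x dose stratum with < %d samples",
        min_samples), call. = FALSE)
    }
    attr(md, "stratified") <- TRUE
  }
  md
}

#' Bimodality-index threshold for a run
#'
#' An explicit `bi_threshold` in the configuration wins; otherwise the
#' convention is 1.1 on full data and 1.3 for stratified (reduced) data, as
#' flagged by [apply_strata()].
#'
#' @param config A [pipeline_config()].
#' @param metadata Sample metadata (possibly carrying the `stratified`
#'   attribute).
#' @return A numeric threshold.
#' @export
resolve_bi_threshold <- function(config, metadata) {
  config$bi_threshold %||%
    (if (isTRUE(attr(metadata, "stratified"))) 1.3 else 1.1)
}

#' Run the complete expression-variability pipeline
#'
#' Orchestrates all stages on a count matrix: size factors, per-dose
#' bimodality exclusion (donor groups pooled), per-stratum EV, whole-data
#' classification anchored in the reference group, split-half
#' cross-validation with binomial confirmation, competing metrics and their
#' Kendall association with expression, exclusive set intersections, and
#' (when a collection is given) over-representation analysis against the
#' per-dose retained-gene backgrounds.
#'
#' @param counts Genes x samples count matrix.
#' @param metadata Sample metadata.
#' @param config A [pipeline_config()].
#' @param gene_sets Optional GMT collection for enrichment.
#' @return A list of class `ev_pipeline_result`: `size_factors`,
#'   `bimodality` (per-dose filter results), `genes_by_dose`, `ev`, `whole`
#'   (labels + thresholds), `classification` (cross-validated), `metrics`,
#'   `taus`, `intersections` (hypo/hyper), `enrichment` (or `NULL`) and a
#'   run `manifest`.
#' @export
run_ev_pipeline <- function(counts, metadata, config = pipeline_config(),
                            gene_sets = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!all(metadata$sample_id %in% colnames(counts))) {
    stop("metadata samples absent from counts [stage: input]", call. = FALSE)
  }
  if (!config$reference_group %in% metadata$donor_group) {
    stop("reference group ", config$reference_group,
         " absent from metadata [stage: input]", call. = FALSE)
  }
  counts <- counts[, metadata$sample_id, drop = FALSE]
  bi_thr <- resolve_bi_threshold(config, metadata)

  sf <- compute_size_factors(counts)

  bim_cfg <- bimodality_config(bi_threshold = bi_thr,
                               zero_percent_thr = config$zero_percent_thr,
                               eps = config$eps, n_starts = config$n_starts,
                               seed = derive_seed(config$seed, "bimodality"))
  doses <- unique(metadata$dose)
  bimodality <- lapply(stats::setNames(doses, doses), function(dose) {
    ids <- metadata$sample_id[metadata$dose == dose]
    filter_bimodal(counts[, ids, drop = FALSE], sf[ids], bim_cfg)
  })
  genes_by_dose <- lapply(bimodality, `[[`, "retained")

  evc <- ev_config(B = config$B, mad_constant = config$mad_constant,
                   loess_span = config$loess_span,
                   loess_degree = config$loess_degree,
                   seed = derive_seed(config$seed, "ev"))
  ev <- compute_ev(counts, metadata, sf, genes_by_dose, evc)
  whole <- classify_whole(ev, config$reference_group, B = config$B,
                          constant = config$mad_constant, k = config$k,
                          seed = derive_seed(config$seed, "classify"))
  classification <- crossvalidate(counts, metadata, sf, genes_by_dose, evc,
                                  reference_group = config$reference_group,
                                  R = config$R, k = config$k,
                                  alpha = config$alpha,
                                  split_by_triplet = config$split_by_triplet,
                                  seed = derive_seed(config$seed, "cv"),
                                  whole = whole)
  metrics <- variability_metrics(counts, metadata, sf, genes_by_dose,
                                 mad_constant = config$mad_constant,
                                 ev_table = ev)
  taus <- metric_vs_expression(metrics)
  intersections <- list(
    hypo = exclusive_intersections(classification, "hypo"),
    hyper = exclusive_intersections(classification, "hyper"))
  enrichment <- if (!is.null(gene_sets)) {
    run_enrichment(classification, gene_sets, genes_by_dose,
                   alpha = config$alpha)
  }
  manifest <- list(
    config = unclass(config), bi_threshold_used = bi_thr,
    n_genes = nrow(counts), n_samples = ncol(counts),
    doses = doses, groups = unique(metadata$donor_group),
    package_version = as.character(utils::packageVersion("exvar")),
    r_version = R.version.string,
    elapsed_seconds = proc.time()[["elapsed"]] - t0)
  structure(list(size_factors = sf, bimodality = bimodality,
                 genes_by_dose = genes_by_dose, ev = ev, whole = whole,
                 classification = classification, metrics = metrics,
                 taus = taus, intersections = intersections,
                 enrichment = enrichment, manifest = manifest),
            class = "ev_pipeline_result")
}

#' Write a pipeline result bundle to TSV files
#'
#' One TSV per stage artifact plus a plain-text manifest echoing the
#' configuration, seed and versions, sufficient to reproduce the run.
#'
#' @param result An `ev_pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (dose in names(result$bimodality)) {
    w(result$bimodality[[dose]]$fits,
      sprintf("bimodality_%sGy.tsv", gsub("[^0-9A-Za-z.]", "_", dose)))
  }
  w(result$ev, "ev.tsv")
  cl <- result$classification
  code <- c(hypo = 1L, non = 2L, hyper = 3L)  # 1 = hypo, 2 = non, 3 = hyper
  cl$label_whole_code <- code[cl$label_whole]
  cl$label_confirmed_code <- code[cl$label_confirmed]
  w(cl, "classification.tsv")
  w(result$metrics, "metrics.tsv")
  w(result$taus, "taus.tsv")
  for (lab in names(result$intersections)) {
    w(result$intersections[[lab]], sprintf("intersections_%s.tsv", lab))
  }
  if (!is.null(result$enrichment)) w(result$enrichment, "enrichment.tsv")
  m <- result$manifest
  writeLines(c(
    "exvar pipeline run manifest",
    paste0("package_version: ", m$package_version),
    paste0("r_version: ", m$r_version),
    paste0("n_genes: ", m$n_genes),
    paste0("n_samples: ", m$n_samples),
    paste0("bi_threshold_used: ", m$bi_threshold_used),
    paste0("elapsed_seconds: ", round(m$elapsed_seconds, 1)),
    "config:",
    paste0("  ", names(m$config), ": ",
           vapply(m$config, function(v) paste(format(v), collapse = ","),
                  character(1)))),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}
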