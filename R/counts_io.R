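#' Read and write count matrices
#'
#' Counts are stored as TSV with gene identifiers in the first column
#' (`gene_id`) and one column per sample. `read_counts()` validates that gene
#' and sample identifiers are unique and that all cells are non-negative
#' integers; `write_counts()` is its inverse (round-trip identity).
#'
#' @param path File path.
#' @return `read_counts()`: an integer matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene id column plus samples",
                          call. = FALSE)
  gene_ids <- as.character(df[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- colnames(df)[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m) || !is.numeric(m)) {
    stop("counts contain missing or non-numeric cells (ragged file?)",
         call. = FALSE)
  }
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count %s at gene %s, sample %s",
                 format(m[bad[1], bad[2]]), gene_ids[bad[1]],
                 sample_ids[bad[2]]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' @rdname read_counts
#' @param counts Genes x samples matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata is a TSV with one row per sample and at least the columns
#' `sample_id`, `donor_group`, `dose`, `triplet_id`; the covariate columns
#' `sex`, `smoking_pack_years` and `alcohol_per_day` are carried along when
#' present.
#'
#' @param path File path.
#' @param counts Optional count matrix; when given, every sample id must
#'   appear among its columns.
#' @return A data.frame.
#' @export
read_metadata <- function(path, counts = NULL) {
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(dose = "character"))
  required <- c("sample_id", "donor_group", "dose", "triplet_id")
  missing <- setdiff(required, colnames(md))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  if (!is.null(counts)) {
    absent <- setdiff(md$sample_id, colnames(counts))
    if (length(absent)) {
      stop("metadata samples absent from counts: ",
           paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    }
  }
  md
}

#' @rdname read_metadata
#' @param metadata Metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference genes of
#' `count_gj / gm_g`, where `gm_g` is the geometric mean of gene g across all
#' samples. Only genes with strictly positive counts in every sample form the
#' reference set; geometric means are computed in log space.
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' compute_size_factors(matrix(c(2, 6, 4, 12), 2,
#'                             dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' @export
compute_size_factors <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  logc <- log(counts)
  log_gm <- rowMeans(logc)
  ok <- is.finite(log_gm)
  if (!any(ok)) {
    stop(paste("no gene has strictly positive counts in all samples;",
               "median-of-ratios is undefined (pseudo-reference fallback",
               "is disabled)"), call. = FALSE)
  }
  log_ratios <- logc[ok, , drop = FALSE] - log_gm[ok]
  sf <- exp(apply(log_ratios, 2, stats::median))
  names(sf) <- colnames(counts)
  sf
}

# subset/align size factors to a matrix's columns; unnamed vectors are taken
# to be in column order
align_size_factors <- function(size_factors, counts) {
  if (is.null(names(size_factors))) {
    if (length(size_factors) != ncol(counts)) {
      stop("size factor length does not match sample count", call. = FALSE)
    }
    names(size_factors) <- colnames(counts)
    return(size_factors)
  }
  missing <- setdiff(colnames(counts), names(size_factors))
  if (length(missing)) {
    stop("size factors missing for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  size_factors[colnames(counts)]
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor.
#'
#' @param counts Genes x samples matrix.
#' @param size_factors Per-sample positive factors, in column order or named
#'   by sample id.
#' @return Numeric matrix of normalized expression values.
#' @export
normalize_counts <- function(counts, size_factors) {
  if (!is.null(names(size_factors)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(size_factors))) {
      stop("size factors missing for some samples", call. = FALSE)
    }
    size_factors <- size_factors[colnames(counts)]
  }
  if (length(size_factors) != ncol(counts)) {
    stop("size factor length does not match sample count", call. = FALSE)
  }
  if (any(size_factors <= 0)) {
    stop("size factors must be strictly positive", call. = FALSE)
  }
  sweep(counts, 2, size_factors, "/")
}
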