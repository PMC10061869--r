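#' Read and write gene-set collections in GMT format
#'
#' GMT files are tab-separated: set name, description, then one member per
#' field. `read_gmt()` preserves set order and rejects duplicate names and
#' lines with fewer than three fields. Members need not belong to any
#' background; intersection with a background happens at test time.
#'
#' @param path File path.
#' @return A named list of character vectors with a `description` attribute
#'   per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop("duplicated set name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    structure(f[-(1:2)], description = f[2])
  })
  stats::setNames(sets, nm)
}

#' @rdname read_gmt
#' @param collection Named list of character vectors (optionally with a
#'   `description` attribute each).
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    desc <- attr(collection[[nm]], "description") %||% nm
    paste(c(nm, desc, as.character(collection[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided hypergeometric over-representation test
#'
#' Tests whether a query gene list overlaps a gene set more than expected
#' when drawing `n = |query|` genes from a background of size `N` containing
#' `K` set members: `p = P(X >= k)` for the observed overlap `k`. The set is
#' intersected with the background before testing.
#'
#' @param query Character vector of query gene ids (must be contained in the
#'   background).
#' @param gene_set Character vector of set members.
#' @param background Character vector: the gene universe.
#' @return One-row data.frame: k, n, K, N, p_hypergeometric, overlap_ids.
#' @examples
#' hypergeom_ora(paste0("g", 1:5), paste0("g", 1:5), paste0("g", 1:20))
#' @export
hypergeom_ora <- function(query, gene_set, background) {
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  background <- unique(background)
  query <- unique(query)
  stray <- setdiff(query, background)
  if (length(stray)) {
    stop("query gene(s) not in background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  set_bg <- intersect(unique(gene_set), background)
  overlap <- intersect(query, set_bg)
  k <- length(overlap); n <- length(query)
  K <- length(set_bg); N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, n = n, K = K, N = N, p_hypergeometric = p,
             overlap_ids = paste(sort(overlap), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, input order restored).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of classified gene sets
#'
#' Runs the hypergeometric test of every collection set against each query:
#' (i) the confirmed hypo-/hyper-variable genes per donor group x dose and
#' (ii) optionally the exclusive-intersection cells of those labels. The
#' background for each dose is the gene list retained after bimodality
#' exclusion at that dose. P-values are BH-adjusted within each query and
#' results filtered at `alpha`.
#'
#' @param classifications A [crossvalidate()] result.
#' @param collection A GMT collection ([read_gmt()]).
#' @param backgrounds Named list (by dose) of background gene id vectors.
#' @param alpha Adjusted-p significance cutoff.
#' @param labels Labels to query.
#' @param label_col Column holding the labels.
#' @param include_intersections Also query exclusive-intersection cells.
#' @return data.frame: query, set, k, n, K, N, p_hypergeometric, p_adjusted,
#'   overlap_ids; only rows with `p_adjusted < alpha`.
#' @export
run_enrichment <- function(classifications, collection, backgrounds,
                           alpha = 0.05, labels = c("hypo", "hyper"),
                           label_col = "label_confirmed",
                           include_intersections = TRUE) {
  queries <- list()
  cl <- classifications
  for (dose in unique(cl$dose)) {
    for (label in labels) {
      for (group in unique(cl$group)) {
        sel <- cl$dose == dose & cl$group == group & cl[[label_col]] == label
        queries[[sprintf("%s|%s|%sGy", label, group, dose)]] <-
          list(genes = unique(cl$gene_id[sel]), dose = dose)
      }
    }
  }
  if (include_intersections) {
    for (label in intersect(labels, c("hypo", "hyper"))) {
      cells <- exclusive_intersections(cl, label, label_col = label_col)
      set_cols <- setdiff(colnames(cells), c("n_genes", "gene_ids"))
      single <- cells[rowSums(as.matrix(cells[, set_cols, drop = FALSE])) == 1L, ,
                      drop = FALSE]
      for (i in seq_len(nrow(single))) {
        set_on <- set_cols[unlist(single[i, set_cols])]
        dose <- sub(".*\\|", "", set_on)
        queries[[sprintf("unique_%s|%s", label, set_on)]] <-
          list(genes = strsplit(single$gene_ids[i], ",")[[1]], dose = dose)
      }
    }
  }
  rows <- list()
  for (qname in names(queries)) {
    q <- queries[[qname]]
    bg <- backgrounds[[q$dose]]
    if (is.null(bg)) stop("no background for dose ", q$dose, call. = FALSE)
    if (length(q$genes) == 0L) next
    res <- do.call(rbind, lapply(names(collection), function(s) {
      cbind(data.frame(query = qname, set = s, stringsAsFactors = FALSE),
            hypergeom_ora(q$genes, collection[[s]], bg))
    }))
    res$p_adjusted <- bh_adjust(res$p_hypergeometric)
    rows[[qname]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(query = character(0), set = character(0), k = integer(0),
               n = integer(0), K = integer(0), N = integer(0),
               p_hypergeometric = numeric(0), p_adjusted = numeric(0),
               overlap_ids = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[!is.na(out$p_adjusted) & out$p_adjusted < alpha, , drop = FALSE]
}
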