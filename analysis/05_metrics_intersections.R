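#!/usr/bin/env Rscript
# Compare EV against the coefficient of variation (CV = SD/mean) and the
# standardized MAD (d = MAD/median): Kendall tau-b of each metric with the
# median expression, per dose. Then decompose the confirmed hypo-/hyper-
# variable sets (3 groups x 3 doses) into exclusive intersection cells.

library(exvar)

counts <- read_counts("results/data/counts.tsv")
meta <- read_metadata("results/data/metadata.tsv", counts)
sfd <- utils::read.delim("results/size_factors.tsv")
sf <- stats::setNames(sfd$size_factor, sfd$sample_id)
ev <- utils::read.delim("results/ev.tsv", colClasses = c(dose = "character"))
cl <- utils::read.delim("results/classification.tsv",
                        colClasses = c(dose = "character"))
genes_by_dose <- lapply(
  stats::setNames(unique(meta$dose), unique(meta$dose)),
  function(d) readLines(sprintf("results/retained_%sGy.txt", d)))

met <- variability_metrics(counts, meta, sf, genes_by_dose, ev_table = ev)
utils::write.table(met, "results/metrics.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
taus <- metric_vs_expression(met)
utils::write.table(taus, "results/taus.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("Kendall tau with median expression (pooled across groups):\n")
print(reshape(taus[taus$group == "pooled", c("metric", "dose", "tau")],
              idvar = "dose", timevar = "metric", direction = "wide"))

for (lab in c("hypo", "hyper")) {
  cells <- exclusive_intersections(cl, lab)
  utils::write.table(cells, sprintf("results/intersections_%s.tsv", lab),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%s-variable: %d genes across %d exclusive cells",
              lab, attr(cells, "n_union"), nrow(cells)))
  # cells exclusive to a single donor group x dose set
  set_cols <- setdiff(colnames(cells), c("n_genes", "gene_ids"))
  single <- cells[rowSums(as.matrix(cells[, set_cols])) == 1, ]
  cat(sprintf("; %d genes unique to one set\n", sum(single$n_genes)))
}
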