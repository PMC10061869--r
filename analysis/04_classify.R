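#!/usr/bin/env Rscript
# Classify genes as hypo-/non-/hyper-variable against the cancer-free (N0)
# reference interval Median_EV +/- 3 * MAD_EV, then confirm labels by
# repeated split-half cross-validation with per-gene binomial tests and
# BH-FDR. Compares confirmed labels to the simulation ground truth.

library(exvar)

counts <- read_counts("results/data/counts.tsv")
meta <- read_metadata("results/data/metadata.tsv", counts)
truth <- utils::read.delim("results/data/truth.tsv",
                           colClasses = c(dose = "character"))
sfd <- utils::read.delim("results/size_factors.tsv")
sf <- stats::setNames(sfd$size_factor, sfd$sample_id)
genes_by_dose <- lapply(
  stats::setNames(unique(meta$dose), unique(meta$dose)),
  function(d) readLines(sprintf("results/retained_%sGy.txt", d)))

cl <- crossvalidate(counts, meta, sf, genes_by_dose,
                    cfg = ev_config(B = 200, seed = 20240503),
                    reference_group = "N0", R = 10, k = 3, alpha = 0.05,
                    seed = 20240504)
utils::write.table(cl, "results/classification.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("label counts (whole data vs confirmed):\n")
print(table(whole = cl$label_whole, dose = cl$dose))
print(table(confirmed = cl$label_confirmed, dose = cl$dose))

tr <- truth[match(paste(cl$gene_id, cl$group, cl$dose),
                  paste(truth$gene_id, truth$group, truth$dose)), ]
for (lab in c("hyper", "hypo")) {
  sel <- tr$true_class == lab
  cat(sprintf(
    "%s: whole-data sensitivity %.2f, confirmed sensitivity %.2f (n = %d)\n",
    lab, mean(cl$label_whole[sel] == lab),
    mean(cl$label_confirmed[sel] == lab), sum(sel)))
}
cat(sprintf("confirmed false-positive rate among true-non genes: %.4f\n",
            mean(cl$label_confirmed[tr$true_class == "non"] != "non")))
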