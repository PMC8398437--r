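#!/usr/bin/env Rscript
# Stage 2 — pairwise co-occurrence testing.
#
# Normalizes abundances (total counts), converts to presence/absence, and
# runs the exact randomized-distribution test on every unordered OTU pair.
# Pairs expected to share <= 1 site are excluded; the rest are classified
# aggregate / segregate / random at alpha = 0.05 (two one-tailed tests, no
# multiplicity adjustment — the classical convention for this model).

suppressPackageStartupMessages(library(phagonet))

tab <- read_otu_table("results/data/abundance.tsv", "results/data/taxonomy.tsv")
tab <- normalize_total_counts(tab)
pa <- to_presence_absence(tab, threshold = 0)
assoc <- test_all_pairs(pa, alpha = 0.05)

dir.create("results", showWarnings = FALSE)
write.table(assoc, "results/associations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Tested", nrow(assoc), "pairs across", length(pa$site_ids), "sites\n")
print(table(assoc$status))
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
if (length(truth$pairs)) {
  sig <- significant_associations(assoc)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  hit <- key(truth$pairs$otu_a, truth$pairs$otu_b) %in%
    key(sig$otu_a, sig$otu_b)
  cat("Planted pairs recovered:", sum(hit), "/", length(hit), "\n")
}
cat("Wrote results/associations.tsv\n")
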