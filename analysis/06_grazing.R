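#!/usr/bin/env Rscript
# Stage 6 — grazing preference.
#
# Scores each bacterial family in a protist association on the 0-3
# palatability index (gram-negative, diazotroph, phototroph), estimates its
# growth rate from genus-level rRNA operon copy numbers (family mean/median;
# families missing from the database or resolved above family are excluded),
# and correlates associated-protist richness with both axes by Kendall
# tau-b. Also annotates candidate interactions (competitive exclusion,
# trophic) from trophic-role labels.

suppressPackageStartupMessages(library(phagonet))

tab <- read_otu_table("results/data/abundance.tsv", "results/data/taxonomy.tsv")
assoc <- read.table("results/associations.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
class(assoc) <- c("assoc_set", "data.frame")
traits <- read.table("results/data/traits.tsv", header = TRUE, sep = "\t")
db <- read.csv("results/data/copy_numbers.csv")
memb <- read.table("results/data/family_membership.tsv", header = TRUE,
                   sep = "\t")

chart <- build_palatability_chart(assoc, tab, traits, db, memb)
print(chart)
write.table(chart$chart, "results/palatability_chart.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(chart$excluded, "results/palatability_exclusions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Palatability score distribution:\n")
print(table(chart$chart$score))

cors <- list()
for (lv in c("genus", "phylum")) for (sg in c("aggregate", "segregate")) {
  for (ax in c("copy_number_mean", "palatability")) {
    key <- paste(lv, sg, ax, sep = "_")
    cors[[key]] <- tryCatch({
      r <- correlate_richness(chart, lv, sg, ax)
      cat(sprintf("tau-b %-45s % .3f (p = %.3f, n = %d, %s)\n", key,
                  r$tau_b, r$p_value, r$n, r$method))
      r[c("tau_b", "p_value", "n", "method")]
    }, error = function(e) {
      cat("tau-b", key, ": not testable (", conditionMessage(e), ")\n")
      NULL
    })
  }
}
jsonlite::write_json(cors, "results/richness_correlations.json",
                     auto_unbox = TRUE, digits = NA)

ii <- infer_interactions(assoc, tab)
write.table(ii$annotations, "results/interaction_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Interaction annotations:\n")
print(table(ii$annotations$annotation))
cat("Wrote palatability chart, correlations and annotations under results/\n")
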