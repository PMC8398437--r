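#!/usr/bin/env Rscript
# Stage 3 — guild association networks.
#
# Builds one unweighted unipartite network per phagotrophic guild from the
# significant associations, exports GraphML + edge lists, and reports the
# composition summary (aggregate share, partner categories with bacteria
# split by phylum). A pair linking two guilds sits in both networks but is
# counted once in the global tally.

suppressPackageStartupMessages(library(phagonet))

tab <- read_otu_table("results/data/abundance.tsv", "results/data/taxonomy.tsv")
assoc <- read.table("results/associations.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
class(assoc) <- c("assoc_set", "data.frame")

nets <- build_guild_networks(assoc, tab)
dir.create("results/networks", recursive = TRUE, showWarnings = FALSE)
for (g in names(nets)) {
  export_network(nets[[g]], file.path("results/networks", paste0(g, ".graphml")),
                 format = "graphml")
  export_network(nets[[g]], file.path("results/networks", paste0(g, "_edges.tsv")),
                 format = "edge_tsv")
}
summ <- summarize_networks(nets, tab)
print(summ)
print(summ$per_guild, row.names = FALSE)
write.table(summ$per_guild, "results/network_guild_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$partner_categories, "results/network_partner_categories.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(total = summ$total, n_aggregate = summ$n_aggregate,
                          n_segregate = summ$n_segregate,
                          aggregate_proportion = summ$aggregate_proportion),
                     "results/network_summary.json", auto_unbox = TRUE,
                     digits = NA)
cat("Wrote per-guild GraphML/edge lists and summaries under results/\n")
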