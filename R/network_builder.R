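#' Build per-guild association networks
#'
#' For each of the five phagotrophic protist guilds, keeps the significant
#' associations (aggregate or segregate) that touch at least one OTU of that
#' guild. An edge linking two guilds appears in both guilds' networks.
#'
#' @param associations An `assoc_set` from [test_all_pairs()].
#' @param table The [otu_table()] carrying functional-group labels.
#' @param guilds Focal groups; defaults to [protist_guilds()].
#' @return Named list of `guild_network` objects, each with elements
#'   `focal_group`, `edges` (otu_a, otu_b, sign, p_lt, p_gt) and `nodes`
#'   (taxonomy rows of all touched OTUs).
#' @export
build_guild_networks <- function(associations, table, guilds = protist_guilds()) {
  stopifnot(inherits(table, "otu_table"))
  sig <- significant_associations(associations)
  fg <- stats::setNames(table$taxonomy$functional_group, table$taxonomy$otu_id)
  out <- list()
  for (g in guilds) {
    touch <- fg[sig$otu_a] == g | fg[sig$otu_b] == g
    edges <- sig[which(touch), c("otu_a", "otu_b", "status", "p_lt", "p_gt"),
                 drop = FALSE]
    names(edges)[3] <- "sign"
    rownames(edges) <- NULL
    ids <- unique(c(edges$otu_a, edges$otu_b))
    nodes <- table$taxonomy[table$taxonomy$otu_id %in% ids, , drop = FALSE]
    rownames(nodes) <- NULL
    out[[g]] <- structure(list(focal_group = g, edges = edges, nodes = nodes),
                          class = "guild_network")
  }
  out
}

#' @export
print.guild_network <- function(x, ...) {
  cat("<guild_network> ", x$focal_group, ": ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "aggregate"), " aggregate, ",
      sum(x$edges$sign == "segregate"), " segregate), ",
      nrow(x$nodes), " nodes\n", sep = "")
  invisible(x)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Summarize guild networks
#'
#' Counts aggregate and segregate edges per guild and globally. The global
#' tally counts each unordered pair once even when an edge sits in two guild
#' networks; the aggregate proportion is `aggregates / (aggregates +
#' segregates)` over that deduplicated union. Partner categories split each
#' guild's edges by the functional group of the non-focal endpoint, with
#' bacteria broken down by phylum.
#'
#' @param networks Result of [build_guild_networks()].
#' @param table The [otu_table()].
#' @param dedup_global Count a guild-overlapping pair once in the global tally
#'   (default TRUE); FALSE sums the per-guild panels instead.
#' @return A `network_summary` list: `total`, `n_aggregate`, `n_segregate`,
#'   `aggregate_proportion`, `per_guild` data frame, `partner_categories`
#'   data frame, `degree` data frame (per-OTU sign breakdown).
#' @export
summarize_networks <- function(networks, table, dedup_global = TRUE) {
  fg <- stats::setNames(table$taxonomy$functional_group, table$taxonomy$otu_id)
  phyl <- stats::setNames(table$taxonomy$phylum, table$taxonomy$otu_id)
  all_edges <- do.call(rbind, c(lapply(networks, function(nw) nw$edges),
                                list(make.row.names = FALSE)))
  if (is.null(all_edges)) {
    all_edges <- data.frame(otu_a = character(), otu_b = character(),
                            sign = character())
  }
  glob <- if (dedup_global && nrow(all_edges)) {
    all_edges[!duplicated(pair_key(all_edges$otu_a, all_edges$otu_b)), ,
              drop = FALSE]
  } else all_edges
  n_agg <- sum(glob$sign == "aggregate")
  n_seg <- sum(glob$sign == "segregate")
  per_guild <- do.call(rbind, lapply(networks, function(nw) {
    data.frame(guild = nw$focal_group,
               n_aggregate = sum(nw$edges$sign == "aggregate"),
               n_segregate = sum(nw$edges$sign == "segregate"))
  }))
  rownames(per_guild) <- NULL
  partner <- do.call(rbind, lapply(networks, function(nw) {
    if (!nrow(nw$edges)) return(NULL)
    g <- nw$focal_group
    partner_of <- ifelse(fg[nw$edges$otu_a] == g, nw$edges$otu_b, nw$edges$otu_a)
    cat_of <- ifelse(fg[partner_of] == "Bacteria",
                     paste0("Bacteria:", phyl[partner_of]), fg[partner_of])
    agg <- stats::aggregate(list(n = seq_along(cat_of)),
                            by = list(guild = rep(g, length(cat_of)),
                                      partner = cat_of,
                                      sign = nw$edges$sign), FUN = length)
    agg
  }))
  degree <- NULL
  if (nrow(glob)) {
    long <- data.frame(otu = c(glob$otu_a, glob$otu_b),
                       sign = rep(glob$sign, 2))
    degree <- stats::aggregate(list(n = seq_len(nrow(long))),
                               by = list(otu = long$otu, sign = long$sign),
                               FUN = length)
  }
  structure(list(total = n_agg + n_seg, n_aggregate = n_agg,
                 n_segregate = n_seg,
                 aggregate_proportion =
                   if (n_agg + n_seg > 0) n_agg / (n_agg + n_seg) else NA_real_,
                 per_guild = per_guild, partner_categories = partner,
                 degree = degree),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> ", x$total, " associations: ", x$n_aggregate,
      " aggregate / ", x$n_segregate, " segregate (",
      if (is.na(x$aggregate_proportion)) "NA" else
        sprintf("%.0f%% aggregate", 100 * x$aggregate_proportion), ")\n",
      sep = "")
  invisible(x)
}

as_igraph <- function(network) {
  nodes <- network$nodes
  ids <- unique(c(network$edges$otu_a, network$edges$otu_b, nodes$otu_id))
  vdf <- data.frame(name = ids,
                    functional_group = nodes$functional_group[match(ids, nodes$otu_id)],
                    taxonomy = nodes$lineage[match(ids, nodes$otu_id)],
                    stringsAsFactors = FALSE)
  edf <- network$edges[, c("otu_a", "otu_b", "sign"), drop = FALSE]
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Export a guild network
#'
#' @param network A `guild_network`.
#' @param path Output file.
#' @param format `"graphml"` (node attributes functional_group/taxonomy, edge
#'   attribute sign; round-trips losslessly through [igraph::read_graph()]) or
#'   `"edge_tsv"` (otu_a, otu_b, sign).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(network, "guild_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format: ", format[1]))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    utils::write.table(network$edges[, c("otu_a", "otu_b", "sign")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
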