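#' Controlled vocabulary of functional groups
#'
#' The eleven community subdivisions used throughout: the five phagotrophic
#' protist guilds that act as response groups, plus the other biotic groupings
#' that serve as explanatory blocks.
#'
#' @return Character vector of valid `functional_group` labels.
#' @export
functional_groups <- function() {
  c("Cercozoa", "Ciliophora", "Amoebozoa", "Discoba",
    "other_phagotrophic_protist",
    "Metazoa", "Fungi", "Chlorophyta", "Streptophyta", "Stramenopiles",
    "Bacteria")
}

#' The five phagotrophic protist response guilds
#' @return Character vector of the five guild labels.
#' @export
protist_guilds <- function() {
  c("Cercozoa", "Ciliophora", "Amoebozoa", "Discoba",
    "other_phagotrophic_protist")
}

#' Construct a site-by-OTU community table
#'
#' The central container: a non-negative site x OTU abundance matrix with a
#' per-OTU taxonomy data frame. Sites are always rows and OTUs columns; both
#' carry explicit id vectors so ordering is never positional-only.
#'
#' @param abundance Numeric matrix, sites in rows, OTUs in columns. Dimnames
#'   are used as ids when `site_ids`/`otu_ids` are not given.
#' @param taxonomy Data frame with one row per OTU and at least the columns
#'   `otu_id`, `lineage`, `rank` (terminal rank: `"family"` for bacteria,
#'   `"genus"` for eukaryotes, or a higher rank), `taxon` (terminal name),
#'   `phylum` and `functional_group`. An optional `trophic_role` column is
#'   consumed by [infer_interactions()].
#' @param site_ids,otu_ids Optional explicit id vectors.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(abundance, taxonomy, site_ids = rownames(abundance),
                      otu_ids = colnames(abundance)) {
  abundance <- as.matrix(abundance)
  if (is.null(site_ids)) site_ids <- paste0("site_", seq_len(nrow(abundance)))
  if (is.null(otu_ids)) otu_ids <- paste0("otu_", seq_len(ncol(abundance)))
  site_ids <- as.character(site_ids)
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(site_ids)) stop("duplicate site ids")
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids")
  if (!is.numeric(abundance)) stop("abundance matrix must be numeric")
  if (anyNA(abundance)) stop("abundance matrix contains missing values")
  if (any(abundance < 0)) stop("negative abundance")
  taxonomy <- as.data.frame(taxonomy)
  req <- c("otu_id", "lineage", "rank", "taxon", "phylum", "functional_group")
  miss <- setdiff(req, names(taxonomy))
  if (length(miss)) stop("taxonomy is missing columns: ", paste(miss, collapse = ", "))
  unmapped <- setdiff(otu_ids, taxonomy$otu_id)
  if (length(unmapped)) {
    stop("OTUs absent from taxonomy: ", paste(unmapped, collapse = ", "))
  }
  bad <- !taxonomy$functional_group %in% functional_groups()
  if (any(bad)) {
    stop("unknown functional_group label(s): ",
         paste(unique(taxonomy$functional_group[bad]), collapse = ", "))
  }
  taxonomy <- taxonomy[match(otu_ids, taxonomy$otu_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  dimnames(abundance) <- list(site_ids, otu_ids)
  structure(list(site_ids = site_ids, otu_ids = otu_ids,
                 abundance = abundance, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("<otu_table> ", length(x$site_ids), " sites x ", length(x$otu_ids),
      " OTUs\n", sep = "")
  tab <- table(x$taxonomy$functional_group)
  cat("  functional groups:",
      paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("<pa_matrix> ", length(x$site_ids), " sites x ", length(x$otu_ids),
      " OTUs; mean occupancy ",
      signif(mean(x$occurrence_count) / length(x$site_ids), 3), "\n", sep = "")
  invisible(x)
}

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_strict <- function(path, delim = NULL, row_names = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- delim_for(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = d, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          row.names = if (row_names) 1 else NULL,
                          comment.char = "", quote = "\"")
  df
}

#' Read an abundance table plus its taxonomy map
#'
#' @param path Abundance file (TSV or CSV; delimiter inferred from the
#'   extension unless `delim` is given). First column holds site ids,
#'   remaining columns one OTU each.
#' @param taxonomy_path Taxonomy file mapping every OTU id (see
#'   [otu_table()] for required columns).
#' @param delim Optional explicit delimiter applied to both files.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, taxonomy_path, delim = NULL) {
  ab <- read_delim_strict(path, delim, row_names = TRUE)
  m <- as.matrix(ab)
  if (!is.numeric(m)) stop("abundance table contains non-numeric cells")
  tax <- read_delim_strict(taxonomy_path, delim)
  otu_table(m, tax)
}

#' Read a site-by-variable abiotic table
#'
#' Columns `x` and `y` are treated as geographic coordinates; everything else
#' must be numeric. A circular `aspect` column (degrees) is expanded into
#' `aspect_sin` and `aspect_cos` so linear models never consume raw degrees.
#' Categorical columns (e.g. a textural class) are rejected: encode texture as
#' numeric sand/silt/clay fractions.
#'
#' @param path TSV/CSV file, first column site ids.
#' @param delim Optional delimiter override.
#' @param site_ids Optional site id vector that the table must match.
#' @return An object of class `abiotic_table` with elements `site_ids`,
#'   `variables` (numeric data frame) and `coordinates` (site x 2 matrix, or
#'   NULL when no x/y columns are present).
#' @export
read_abiotic_table <- function(path, delim = NULL, site_ids = NULL) {
  df <- read_delim_strict(path, delim, row_names = TRUE)
  abiotic_table(df, site_ids = site_ids)
}

#' Construct an abiotic table from a data frame
#' @param df Data frame with site rownames; see [read_abiotic_table()].
#' @param site_ids Optional site ids the rows must match (same order).
#' @return An `abiotic_table`.
#' @export
abiotic_table <- function(df, site_ids = NULL) {
  df <- as.data.frame(df)
  if (anyNA(df)) {
    bad <- names(df)[vapply(df, anyNA, logical(1))]
    stop("missing values in abiotic columns: ", paste(bad, collapse = ", "))
  }
  chr <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(chr)) {
    stop("non-numeric abiotic column(s): ", paste(chr, collapse = ", "),
         ". Encode categorical texture as numeric fractions (sand/silt/clay).")
  }
  ids <- rownames(df)
  if (is.null(ids)) ids <- paste0("site_", seq_len(nrow(df)))
  if (!is.null(site_ids) && !identical(as.character(ids), as.character(site_ids))) {
    stop("abiotic site ids do not match the community table")
  }
  coords <- NULL
  if (all(c("x", "y") %in% names(df))) {
    coords <- as.matrix(df[, c("x", "y")])
    rownames(coords) <- ids
    df <- df[, setdiff(names(df), c("x", "y")), drop = FALSE]
  }
  if ("aspect" %in% names(df)) {
    rad <- df$aspect * pi / 180
    df$aspect_sin <- sin(rad)
    df$aspect_cos <- cos(rad)
    df$aspect <- NULL
  }
  rownames(df) <- ids
  structure(list(site_ids = as.character(ids), variables = df,
                 coordinates = coords),
            class = "abiotic_table")
}

#' Total-counts normalization
#'
#' Divides each site row by its row total and multiplies by `scale`, so all
#' row sums equal `scale`. This is the classic library-size correction for
#' uneven sequencing depth.
#'
#' @param table An [otu_table()].
#' @param scale Positive real; target row sum (default 1).
#' @return A normalized `otu_table`.
#' @export
normalize_total_counts <- function(table, scale = 1) {
  stopifnot(inherits(table, "otu_table"), scale > 0)
  rs <- rowSums(table$abundance)
  if (any(rs == 0)) {
    stop("zero-sum site row(s): ",
         paste(table$site_ids[rs == 0], collapse = ", "))
  }
  out <- table
  out$abundance <- table$abundance / rs * scale
  out
}

#' Convert abundances to presence/absence
#'
#' @param table An [otu_table()].
#' @param threshold Detection floor: presence is `abundance > threshold`.
#'   Defaults to 0 (any non-zero abundance counts as present).
#' @return An object of class `pa_matrix` with elements `site_ids`, `otu_ids`,
#'   `presence` (binary matrix) and `occurrence_count` (per-OTU number of
#'   occupied sites).
#' @export
to_presence_absence <- function(table, threshold = 0) {
  stopifnot(inherits(table, "otu_table"), threshold >= 0)
  pres <- (table$abundance > threshold) * 1L
  structure(list(site_ids = table$site_ids, otu_ids = table$otu_ids,
                 presence = pres, occurrence_count = colSums(pres)),
            class = "pa_matrix")
}

#' Select the OTUs of one functional group
#'
#' @param table An [otu_table()].
#' @param group A label from [functional_groups()], or `"all_biota"`, which
#'   returns every OTU *not* in `response_group` (the guild under test), so an
#'   all-biota explanatory block never contains its own response.
#' @param response_group Required when `group == "all_biota"`.
#' @return An `otu_table` restricted to the selected OTUs (possibly with zero
#'   OTUs; downstream stages treat an empty selection as not testable).
#' @export
select_group <- function(table, group, response_group = NULL) {
  stopifnot(inherits(table, "otu_table"))
  fg <- table$taxonomy$functional_group
  if (identical(group, "all_biota")) {
    if (is.null(response_group)) {
      stop("'all_biota' selection needs the response_group to exclude")
    }
    if (!response_group %in% functional_groups()) {
      stop("unknown functional group label: ", response_group)
    }
    keep <- fg != response_group
  } else {
    if (!group %in% functional_groups()) {
      stop("unknown functional group label: ", group)
    }
    keep <- fg == group
  }
  out <- table
  out$otu_ids <- table$otu_ids[keep]
  out$abundance <- table$abundance[, keep, drop = FALSE]
  out$taxonomy <- table$taxonomy[keep, , drop = FALSE]
  rownames(out$taxonomy) <- NULL
  out
}

#' Write a site-by-OTU table (sites in rows) as TSV
#' @param table An [otu_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(site_id = table$site_ids,
                   as.data.frame(table$abundance), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
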