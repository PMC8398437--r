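#' Palatability score of a bacterial family
#'
#' One point for each trait that increases palatability to bacterivorous
#' protists: gram-negative cell wall, nitrogen fixation (diazotroph), carbon
#' fixation (phototroph). A gram-negative nitrogen-fixing phototroph scores
#' 3; a gram-positive heterotroph scores 0.
#'
#' @param gram_negative,diazotroph,phototroph Logical/0-1 (vectorized).
#' @return Integer score(s) 0-3.
#' @export
palatability_score <- function(gram_negative, diazotroph, phototroph) {
  flags <- cbind(gram_negative, diazotroph, phototroph)
  if (anyNA(flags)) stop("missing trait flag")
  if (!all(flags %in% c(0, 1))) stop("trait flags must be 0/1 or logical")
  as.integer(rowSums(flags))
}

#' Estimate a family-level rRNA operon copy number
#'
#' rRNA copy number proxies maximal growth rate but databases report it at
#' genus level; a family estimate is the mean and median over the genera of
#' that family found in the database. Families with no genus in the database
#' are excluded (`excluded_not_in_db`), as are OTUs whose terminal rank is
#' above family (`excluded_rank_above_family`) — exclusions are statuses,
#' not errors.
#'
#' @param db Data frame with columns `genus`, `copy_number` (one row per
#'   genus, pre-aggregated).
#' @param membership Data frame `family`, `genus` mapping families to genera.
#' @param family Family id.
#' @param rank Terminal rank of the OTU carrying the family (default
#'   `"family"`).
#' @return A `copy_number_estimate` list: `family`, `genus_values`, `mean`,
#'   `median`, `status`.
#' @export
estimate_family_copy_number <- function(db, membership, family,
                                        rank = "family") {
  stopifnot(all(c("genus", "copy_number") %in% names(db)),
            all(c("family", "genus") %in% names(membership)))
  if (!identical(rank, "family")) {
    return(structure(list(family = family, genus_values = numeric(0),
                          mean = NA_real_, median = NA_real_,
                          status = "excluded_rank_above_family"),
                     class = "copy_number_estimate"))
  }
  genera <- membership$genus[membership$family == family]
  vals <- db$copy_number[db$genus %in% genera]
  if (!length(vals)) {
    return(structure(list(family = family, genus_values = numeric(0),
                          mean = NA_real_, median = NA_real_,
                          status = "excluded_not_in_db"),
                     class = "copy_number_estimate"))
  }
  structure(list(family = family, genus_values = vals,
                 mean = mean(vals), median = stats::median(vals),
                 status = "ok"),
            class = "copy_number_estimate")
}

#' Build the palatability chart
#'
#' One record per bacterial family that (i) appears in at least one
#' significant association with a phagotrophic protist and (ii) survives the
#' copy-number exclusions. Richness of associated protists is counted as
#' distinct taxa at genus and at phylum level, separately for aggregate and
#' segregate associations.
#'
#' @param associations An `assoc_set`.
#' @param table The [otu_table()].
#' @param traits Data frame `family`, `gram_negative`, `diazotroph`,
#'   `phototroph` (0/1).
#' @param db,membership Copy-number inputs, see
#'   [estimate_family_copy_number()].
#' @return A `palatability_chart` list: `chart` data frame (family, score,
#'   copy_number_mean, copy_number_median, richness_genus_aggregate,
#'   richness_genus_segregate, richness_phylum_aggregate,
#'   richness_phylum_segregate), `associated_protists` (long data frame
#'   family/protist/guild/protist_genus/protist_phylum/sign), `excluded`
#'   data frame (family, reason).
#' @export
build_palatability_chart <- function(associations, table, traits, db,
                                     membership) {
  stopifnot(inherits(table, "otu_table"))
  tax <- table$taxonomy
  fg <- stats::setNames(tax$functional_group, tax$otu_id)
  sig <- significant_associations(associations)
  is_prot <- function(o) fg[o] %in% protist_guilds()
  is_bact <- function(o) fg[o] == "Bacteria"
  pb <- sig[(is_prot(sig$otu_a) & is_bact(sig$otu_b)) |
              (is_bact(sig$otu_a) & is_prot(sig$otu_b)), , drop = FALSE]
  if (!nrow(pb)) {
    return(structure(list(chart = data.frame(), associated_protists = data.frame(),
                          excluded = data.frame()),
                     class = "palatability_chart"))
  }
  bact <- ifelse(is_bact(pb$otu_a), pb$otu_a, pb$otu_b)
  prot <- ifelse(is_bact(pb$otu_a), pb$otu_b, pb$otu_a)
  long <- data.frame(
    bact_otu = bact,
    family = tax$taxon[match(bact, tax$otu_id)],
    rank = tax$rank[match(bact, tax$otu_id)],
    protist = prot,
    guild = fg[prot],
    protist_genus = tax$taxon[match(prot, tax$otu_id)],
    protist_phylum = tax$phylum[match(prot, tax$otu_id)],
    sign = pb$status, stringsAsFactors = FALSE)
  fams <- unique(long[, c("family", "rank")])
  chart_rows <- list(); excl_rows <- list()
  for (i in seq_len(nrow(fams))) {
    fam <- fams$family[i]
    est <- estimate_family_copy_number(db, membership, fam,
                                       rank = fams$rank[i])
    if (est$status != "ok") {
      excl_rows[[length(excl_rows) + 1]] <-
        data.frame(family = fam, reason = est$status)
      next
    }
    tr <- traits[traits$family == fam, , drop = FALSE]
    if (!nrow(tr)) {
      excl_rows[[length(excl_rows) + 1]] <-
        data.frame(family = fam, reason = "excluded_no_trait_record")
      next
    }
    sub <- long[long$family == fam, , drop = FALSE]
    rich <- function(col, sg) length(unique(sub[[col]][sub$sign == sg]))
    chart_rows[[length(chart_rows) + 1]] <- data.frame(
      family = fam,
      score = palatability_score(tr$gram_negative[1], tr$diazotroph[1],
                                 tr$phototroph[1]),
      copy_number_mean = est$mean, copy_number_median = est$median,
      richness_genus_aggregate = rich("protist_genus", "aggregate"),
      richness_genus_segregate = rich("protist_genus", "segregate"),
      richness_phylum_aggregate = rich("protist_phylum", "aggregate"),
      richness_phylum_segregate = rich("protist_phylum", "segregate"))
  }
  chart <- if (length(chart_rows)) do.call(rbind, chart_rows) else data.frame()
  excluded <- if (length(excl_rows)) do.call(rbind, excl_rows) else
    data.frame(family = character(), reason = character())
  structure(list(chart = chart, associated_protists = long,
                 excluded = excluded),
            class = "palatability_chart")
}

#' @export
print.palatability_chart <- function(x, ...) {
  cat("<palatability_chart> ", nrow(x$chart), " families charted, ",
      nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Kendall tau-b rank correlation with tie correction
#'
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` with C/D the concordant and
#' discordant pair counts, `n0 = n(n-1)/2` and `n1`, `n2` the tie sums of
#' the two margins.
#'
#' @param x,y Numeric vectors of equal length.
#' @return tau-b, or NA with a warning when either margin is constant.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  conc_disc <- sum((dx * dy)[up])
  n0 <- n * (n - 1) / 2
  tie_sum <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_sum(x); n2 <- tie_sum(y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    warning("tau-b undefined: a margin is constant")
    return(NA_real_)
  }
  conc_disc / denom
}

#' Kendall tau-b test
#'
#' Two-sided p-value: exact permutation enumeration for n <= `exact_max`
#' (all n! orderings of `y`, counting orderings with `|tau_b| >=` the
#' observed), otherwise the normal approximation with the full tie-corrected
#' variance of C - D.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest n for exact enumeration (default 10).
#' @return List with `tau_b`, `p_value`, `method`.
#' @export
kendall_tau_b_test <- function(x, y, exact_max = 10) {
  n <- length(x)
  tb <- kendall_tau_b(x, y)
  if (is.na(tb)) return(list(tau_b = NA_real_, p_value = NA_real_,
                             method = "undefined"))
  if (n <= exact_max) {
    p <- tau_exact_perm_p(as.numeric(x), as.numeric(y))
    return(list(tau_b = tb, p_value = p, method = "exact_permutation"))
  }
  # normal approximation for S = C - D with ties (Kendall 1970)
  tx <- table(x); ty <- table(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  dxy <- sign(outer(x, x, "-")) * sign(outer(y, y, "-"))
  S <- sum(dxy[upper.tri(dxy)])
  z <- S / sqrt(var_s)
  list(tau_b = tb, p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       method = "normal_approximation")
}

#' Correlate protist richness with prey traits
#'
#' Tests whether the richness of protists associated with bacterial families
#' (at genus or phylum level, for one association sign) tracks the families'
#' growth-rate proxy or palatability score.
#'
#' @param chart A `palatability_chart`.
#' @param level `"genus"` or `"phylum"` richness.
#' @param sign `"aggregate"` or `"segregate"` associations.
#' @param axis `"copy_number_mean"`, `"copy_number_median"` or
#'   `"palatability"`.
#' @param exact_max Passed to [kendall_tau_b_test()].
#' @return List with `tau_b`, `p_value`, `method`, `n` (families with at
#'   least one association of the requested sign).
#' @export
correlate_richness <- function(chart,
                               level = c("genus", "phylum"),
                               sign = c("aggregate", "segregate"),
                               axis = c("copy_number_mean",
                                        "copy_number_median", "palatability"),
                               exact_max = 10) {
  stopifnot(inherits(chart, "palatability_chart"))
  level <- match.arg(level); sign <- match.arg(sign); axis <- match.arg(axis)
  df <- chart$chart
  rich_col <- paste0("richness_", level, "_", sign)
  df <- df[df[[rich_col]] > 0, , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 chart records with sign ", sign)
  xv <- if (axis == "palatability") df$score else df[[axis]]
  yv <- df[[rich_col]]
  res <- kendall_tau_b_test(xv, yv, exact_max = exact_max)
  res$n <- nrow(df)
  res
}

predator_prey_map <- function() {
  list(bacterivore = "Bacteria",
       cytophage = protist_guilds(),
       predator = c(protist_guilds(), "Metazoa", "Fungi"),
       omnivore = c("Bacteria", protist_guilds(), "Metazoa", "Fungi"))
}

#' Annotate candidate biological interactions
#'
#' Literature-style inference rules on significant associations: a segregate
#' between two OTUs sharing a trophic role suggests competitive exclusion; an
#' aggregate between an OTU with a consumer role and an OTU whose functional
#' group is eligible prey for that role suggests a trophic relationship.
#' Annotations never overwrite association statistics; pairs with missing
#' role labels are skipped and logged.
#'
#' @param associations An `assoc_set`.
#' @param table [otu_table()] whose taxonomy carries a `trophic_role` column.
#' @param prey_map Named list: consumer role -> eligible prey functional
#'   groups (default [predator_prey_map()] semantics).
#' @return List with `annotations` (association columns + `annotation`) and
#'   `skipped` (data frame otu_a/otu_b/reason).
#' @export
infer_interactions <- function(associations, table,
                               prey_map = predator_prey_map()) {
  stopifnot(inherits(table, "otu_table"))
  tax <- table$taxonomy
  if (!"trophic_role" %in% names(tax)) {
    stop("taxonomy has no trophic_role column")
  }
  role <- stats::setNames(tax$trophic_role, tax$otu_id)
  fg <- stats::setNames(tax$functional_group, tax$otu_id)
  sig <- significant_associations(associations)
  ann <- character(nrow(sig))
  skipped <- list()
  keep <- rep(TRUE, nrow(sig))
  for (i in seq_len(nrow(sig))) {
    a <- sig$otu_a[i]; b <- sig$otu_b[i]
    ra <- role[a]; rb <- role[b]
    if (is.na(ra) || is.na(rb) || !nzchar(ra) || !nzchar(rb)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(otu_a = a, otu_b = b, reason = "missing trophic role")
      keep[i] <- FALSE
      next
    }
    if (sig$status[i] == "segregate" && ra == rb) {
      ann[i] <- "competitive_exclusion_candidate"
    } else if (sig$status[i] == "aggregate") {
      eats <- function(rc, prey_otu) {
        !is.null(prey_map[[rc]]) && fg[prey_otu] %in% prey_map[[rc]]
      }
      if (eats(ra, b) || eats(rb, a)) ann[i] <- "trophic_candidate"
    }
  }
  out <- sig[keep, , drop = FALSE]
  out$annotation <- ann[keep]
  out <- out[out$annotation != "", , drop = FALSE]
  rownames(out) <- NULL
  list(annotations = out,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(otu_a = character(), otu_b = character(),
                    reason = character()))
}
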