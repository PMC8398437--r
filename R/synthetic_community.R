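#' Configuration for the synthetic community generator
#'
#' @param n_sites Number of sites (>= 4).
#' @param n_otus Named integer vector: OTUs per functional group (names from
#'   [functional_groups()]).
#' @param occupancy_range Length-2 numeric in \[0,1\]: per-OTU baseline
#'   occupancy probabilities are drawn uniformly from this range.
#' @param planted_pairs Data frame with columns `otu_a`, `otu_b` (integer
#'   indices into the generated OTU set or character ids), `sign`
#'   (`"aggregate"`/`"segregate"`) and `strength` in \[0,1\]. May have 0 rows.
#' @param n_env_otus Number of OTUs whose occupancy tracks the environmental
#'   gradient (on top of the planted pairs, never overlapping them).
#' @param env_effect Effect size on the logit-occupancy scale per SD of the
#'   gradient for environment-driven OTUs.
#' @param collinear_pair_r Target sample Pearson correlation engineered
#'   between the `ctn_ratio` and `total_c` abiotic columns.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters for
#'   abundances conditional on presence.
#' @param seed Integer seed; the whole community is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 18,
                       n_otus = c(Cercozoa = 8, Bacteria = 12),
                       occupancy_range = c(0.3, 0.7),
                       planted_pairs = NULL,
                       n_env_otus = 0,
                       env_effect = 2,
                       collinear_pair_r = 0.85,
                       abundance_meanlog = 3,
                       abundance_sdlog = 1,
                       seed = 1L) {
  if (n_sites < 4) stop("n_sites must be >= 4")
  if (is.null(names(n_otus)) || !all(names(n_otus) %in% functional_groups())) {
    stop("n_otus must be named with functional group labels")
  }
  if (any(occupancy_range < 0) || any(occupancy_range > 1)) {
    stop("occupancy probabilities must lie in [0,1]")
  }
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(otu_a = integer(), otu_b = integer(),
                                sign = character(), strength = numeric())
  }
  planted_pairs <- as.data.frame(planted_pairs)
  if (nrow(planted_pairs)) {
    stopifnot(all(c("otu_a", "otu_b", "sign", "strength") %in% names(planted_pairs)),
              all(planted_pairs$sign %in% c("aggregate", "segregate")),
              all(planted_pairs$strength >= 0 & planted_pairs$strength <= 1))
    key <- apply(planted_pairs[, c("otu_a", "otu_b")], 1,
                 function(r) paste(sort(r), collapse = "|"))
    if (anyDuplicated(key)) stop("an OTU pair is planted twice")
  }
  structure(list(n_sites = as.integer(n_sites), n_otus = n_otus,
                 occupancy_range = occupancy_range,
                 planted_pairs = planted_pairs,
                 n_env_otus = as.integer(n_env_otus),
                 env_effect = env_effect,
                 collinear_pair_r = collinear_pair_r,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset emulating an 18-site polar desert survey
#'
#' 18 sites; 90 phagotrophic protist OTUs split over the five guilds; 80
#' bacterial families spanning 12 phyla; a handful of metazoan, fungal, plant
#' and stramenopile OTUs; ten planted pairs (7 aggregate, 3 segregate).
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
mdv_like_preset <- function(seed = 1L) {
  n_otus <- c(Cercozoa = 30, Ciliophora = 20, Amoebozoa = 15, Discoba = 10,
              other_phagotrophic_protist = 15,
              Metazoa = 5, Fungi = 3, Chlorophyta = 3, Streptophyta = 5,
              Stramenopiles = 4, Bacteria = 80)
  # pairs indexed into the OTU layout (protist guilds first, Bacteria last):
  # protist-bacteria aggregates/segregates plus a couple of protist-protist ones
  n_prot <- 90
  planted <- data.frame(
    otu_a = c(1L, 2L, 31L, 51L, 66L, 5L, 32L, 3L, 52L, 33L),
    otu_b = c(111L, 112L, 113L, 114L, 115L, 34L, 67L, 121L, 122L, 123L),
    sign = c(rep("aggregate", 7), rep("segregate", 3)),
    strength = c(0.9, 0.85, 0.9, 0.8, 0.85, 0.9, 0.8, 0.95, 0.9, 0.85))
  stopifnot(all(planted$otu_b <= n_prot + 80 + 20))
  sim_config(n_sites = 18, n_otus = n_otus,
             occupancy_range = c(0.3, 0.7),
             planted_pairs = planted,
             n_env_otus = 20, env_effect = 2.5,
             collinear_pair_r = 0.85, seed = seed)
}

bacterial_phyla <- function() {
  c("Proteobacteria", "Actinobacteria", "Chloroflexi", "Acidobacteria",
    "Bacteroidetes", "Firmicutes", "Cyanobacteria", "Verrucomicrobia",
    "Planctomycetes", "Gemmatimonadetes", "Deinococcus-Thermus", "Nitrospirae")
}

sim_taxonomy <- function(n_otus) {
  rows <- list()
  idx <- 0L
  phyl_for <- function(group, i) {
    switch(group,
           Cercozoa = "Cercozoa", Ciliophora = "Ciliophora",
           Amoebozoa = "Amoebozoa", Discoba = "Discoba",
           other_phagotrophic_protist = c("Stramenopiles", "Apusomonadida",
                                          "Telonemia")[(i %% 3) + 1],
           Metazoa = c("Nematoda", "Rotifera", "Tardigrada")[(i %% 3) + 1],
           Fungi = "Basidiomycota", Chlorophyta = "Chlorophyta",
           Streptophyta = "Streptophyta", Stramenopiles = "Ochrophyta",
           Bacteria = bacterial_phyla()[(i %% 12) + 1])
  }
  role_for <- function(group, i) {
    switch(group,
           Cercozoa = , Ciliophora = , Discoba = ,
           other_phagotrophic_protist =
             if (i %% 7 == 0) "cytophage" else "bacterivore",
           Amoebozoa = if (i %% 5 == 0) "omnivore" else "bacterivore",
           Metazoa = c("bacterivore", "predator")[(i %% 5 == 0) + 1],
           Fungi = "prey_eligible",
           Chlorophyta = , Streptophyta = "phototroph",
           Stramenopiles = "phototroph",
           Bacteria = "prey_eligible")
  }
  for (group in names(n_otus)) {
    n <- n_otus[[group]]
    if (n == 0) next
    for (i in seq_len(n)) {
      idx <- idx + 1L
      phylum <- phyl_for(group, i)
      if (group == "Bacteria") {
        # every ~10th bacterial OTU is only resolved above family
        above <- i %% 10 == 0
        taxon <- if (above) sprintf("ud_class_%02d", i) else
          sprintf("fam_%s_%02d", substr(phylum, 1, 4), i)
        rank <- if (above) "class" else "family"
      } else {
        taxon <- sprintf("gen_%s_%02d", substr(group, 1, 4), i)
        rank <- "genus"
      }
      rows[[idx]] <- data.frame(
        otu_id = sprintf("otu_%03d", idx),
        lineage = paste(phylum, taxon, sep = ";"),
        rank = rank, taxon = taxon, phylum = phylum,
        functional_group = group,
        trophic_role = role_for(group, i))
    }
  }
  do.call(rbind, rows)
}

# exact-correlation construction: returns a vector whose sample Pearson
# correlation with `base` equals r exactly
collinear_with <- function(base, r, noise) {
  z1 <- scale(base)[, 1]
  e <- stats::residuals(stats::lm(noise ~ z1))
  e <- e / stats::sd(e)
  z1 * r + sqrt(1 - r^2) * e
}

sim_abiotic <- function(n_sites, gradient, collinear_pair_r) {
  total_c <- 2 + 0.8 * gradient + stats::rnorm(n_sites, 0, 0.5)
  elev <- 200 + 150 * stats::rnorm(n_sites)
  df <- data.frame(
    moisture = pmax(0.5, 4 + 2 * gradient + stats::rnorm(n_sites, 0, 1.5)),
    ph = 8.5 + 0.5 * stats::rnorm(n_sites),
    ec = exp(stats::rnorm(n_sites, 0, 0.6)),
    total_n = pmax(0.01, 0.2 + 0.05 * gradient + stats::rnorm(n_sites, 0, 0.08)),
    total_p = pmax(0.01, 0.6 + stats::rnorm(n_sites, 0, 0.15)),
    total_c = total_c,
    ctn_ratio = collinear_with(total_c, collinear_pair_r,
                               stats::rnorm(n_sites)) * 3 + 12,
    no3_n = exp(stats::rnorm(n_sites, 1, 0.7)),
    distance_to_coast = NA_real_,
    elevation = elev,
    aspect = stats::runif(n_sites, 0, 360),
    sand_fraction = pmin(0.95, pmax(0.4, 0.8 + stats::rnorm(n_sites, 0, 0.1))),
    x = stats::runif(n_sites, 0, 50),
    y = stats::runif(n_sites, 0, 50))
  # distance to coast tracks elevation strongly (> 0.70), as in real MDV
  # transects, so the collinearity screen has a second pair to act on
  df$distance_to_coast <- pmax(0.1, collinear_with(elev, 0.8,
                                                   stats::rnorm(n_sites)) * 8 + 20)
  rownames(df) <- sprintf("site_%02d", seq_len(n_sites))
  df
}

sim_traits <- function(taxonomy) {
  fam <- taxonomy[taxonomy$functional_group == "Bacteria" &
                    taxonomy$rank == "family", ]
  gram_pos_phyla <- c("Actinobacteria", "Firmicutes", "Deinococcus-Thermus",
                      "Chloroflexi")
  data.frame(
    family = fam$taxon,
    gram_negative = as.integer(!fam$phylum %in% gram_pos_phyla),
    diazotroph = as.integer(fam$phylum == "Cyanobacteria" |
                              (fam$phylum == "Proteobacteria" &
                                 seq_len(nrow(fam)) %% 5 == 0)),
    phototroph = as.integer(fam$phylum %in% c("Cyanobacteria", "Chloroflexi") &
                              seq_len(nrow(fam)) %% 2 == 0))
}

sim_copy_numbers <- function(taxonomy) {
  fam <- taxonomy[taxonomy$functional_group == "Bacteria" &
                    taxonomy$rank == "family", ]
  slow_phyla <- c("Actinobacteria", "Deinococcus-Thermus", "Chloroflexi",
                  "Acidobacteria")
  rows <- list(); memb <- list()
  for (i in seq_len(nrow(fam))) {
    if (i %% 9 == 0) next  # family absent from the copy-number database
    k <- 1 + (i %% 4)
    base <- if (fam$phylum[i] %in% slow_phyla) 1.5 else 3.5
    cn <- pmin(9, pmax(1, round(base + stats::rnorm(k, 0, 1.2))))
    genera <- sprintf("%s_gen%d", fam$taxon[i], seq_len(k))
    rows[[length(rows) + 1]] <- data.frame(genus = genera, copy_number = cn)
    memb[[length(memb) + 1]] <- data.frame(family = fam$taxon[i], genus = genera)
  }
  list(db = do.call(rbind, rows), membership = do.call(rbind, memb))
}

#' Generate a synthetic community with planted association structure
#'
#' Null OTUs occupy sites as mutually independent Bernoulli draws. A planted
#' pair with strength `s` is coupled per site: with probability `s` both OTUs
#' threshold one shared uniform (comonotone for aggregates, antithetic for
#' segregates), otherwise they draw independently. Co-presence probability is
#' therefore exactly `s*min(pa,pb) + (1-s)*pa*pb` for aggregates and
#' `s*max(0, pa+pb-1) + (1-s)*pa*pb` for segregates; strength-1 segregation
#' between OTUs whose occupancies sum to more than 1 is infeasible and
#' rejected. Abundances conditional on presence are log-normal. Environment-
#' driven OTUs shift their occupancy along a latent gradient on the logit
#' scale; the same gradient leaks into moisture/total C so abiotic tables are
#' realistically structured.
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` ([otu_table()]), `abiotic`
#'   ([abiotic_table()]), `traits` (family trait data frame), `copy_numbers`
#'   (list `db` = genus/copy_number data frame, `membership` = family/genus
#'   map) and `truth` (planted ground truth: `pairs`, `env_driven_otus`,
#'   `occupancy`).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  n_sites <- config$n_sites
  taxonomy <- sim_taxonomy(config$n_otus)
  n_otu <- nrow(taxonomy)
  otu_ids <- taxonomy$otu_id

  planted <- config$planted_pairs
  if (nrow(planted)) {
    to_id <- function(v) if (is.numeric(v)) otu_ids[v] else as.character(v)
    planted$otu_a <- to_id(planted$otu_a)
    planted$otu_b <- to_id(planted$otu_b)
    if (anyNA(c(planted$otu_a, planted$otu_b)) ||
        !all(c(planted$otu_a, planted$otu_b) %in% otu_ids)) {
      stop("planted pair references an OTU outside the generated set")
    }
  }

  occ <- stats::runif(n_otu, config$occupancy_range[1], config$occupancy_range[2])
  names(occ) <- otu_ids

  if (nrow(planted)) {
    infeasible <- planted$sign == "segregate" & planted$strength == 1 &
      occ[planted$otu_a] + occ[planted$otu_b] > 1
    if (any(infeasible)) {
      stop("infeasible planted segregate(s): exclusivity caps total occupancy ",
           "but occupancies sum above 1 for pair(s) ",
           paste(which(infeasible), collapse = ", "))
    }
  }

  planted_otus <- unique(c(planted$otu_a, planted$otu_b))
  free <- setdiff(otu_ids, planted_otus)
  env_driven <- character(0)
  gradient <- as.numeric(scale(stats::rnorm(n_sites)))
  if (config$n_env_otus > 0) {
    env_driven <- free[seq_len(min(config$n_env_otus, length(free)))]
  }

  presence <- matrix(0L, n_sites, n_otu, dimnames = list(NULL, otu_ids))
  # independent (possibly env-modulated) occupancies
  for (o in setdiff(otu_ids, planted_otus)) {
    p <- if (o %in% env_driven) {
      stats::plogis(stats::qlogis(occ[o]) + config$env_effect * gradient)
    } else rep(occ[o], n_sites)
    presence[, o] <- as.integer(stats::runif(n_sites) < p)
  }
  # coupled planted pairs
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      a <- planted$otu_a[i]; b <- planted$otu_b[i]
      s <- planted$strength[i]
      couple <- stats::runif(n_sites) < s
      u <- stats::runif(n_sites)
      ua <- ifelse(couple, u, stats::runif(n_sites))
      ub <- if (planted$sign[i] == "aggregate") {
        ifelse(couple, u, stats::runif(n_sites))
      } else {
        ifelse(couple, 1 - u, stats::runif(n_sites))
      }
      presence[, a] <- as.integer(ua < occ[a])
      presence[, b] <- as.integer(ub < occ[b])
    }
  }

  abund <- presence *
    matrix(stats::rlnorm(n_sites * n_otu, config$abundance_meanlog,
                         config$abundance_sdlog), n_sites, n_otu)
  rownames(abund) <- sprintf("site_%02d", seq_len(n_sites))
  table <- otu_table(abund, taxonomy)

  abiotic <- abiotic_table(sim_abiotic(n_sites, gradient, config$collinear_pair_r))
  traits <- sim_traits(taxonomy)
  cn <- sim_copy_numbers(taxonomy)

  truth <- list(pairs = planted, env_driven_otus = env_driven,
                occupancy = occ, gradient = gradient, seed = config$seed)
  list(table = table, abiotic = abiotic, traits = traits,
       copy_numbers = cn, truth = truth)
}

#' Write all generator outputs as plain-text tables plus a truth JSON
#' @param community Result of [generate_community()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_community <- function(community, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(community$table, file.path(outdir, "abundance.tsv"))
  utils::write.table(community$table$taxonomy, file.path(outdir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- data.frame(site_id = community$abiotic$site_ids,
                   community$abiotic$variables,
                   community$abiotic$coordinates, check.names = FALSE)
  utils::write.table(ab, file.path(outdir, "abiotic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$traits, file.path(outdir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(community$copy_numbers$db,
                     file.path(outdir, "copy_numbers.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(community$copy_numbers$membership,
                     file.path(outdir, "family_membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(community$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
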