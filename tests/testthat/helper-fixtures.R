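# Shared fixtures and independent oracles for the suite.

# exhaustive-enumeration oracle for the co-occurrence model: place OTU a on
# the first n_a sites, enumerate every placement of OTU b, tally overlaps
enum_pmf <- function(N, n_a, n_b) {
  a_sites <- seq_len(n_a)
  if (n_b == 0) {
    counts <- c(`0` = 1)
  } else {
    subsets <- utils::combn(N, n_b)
    overlaps <- apply(subsets, 2, function(s) sum(s %in% a_sites))
    counts <- table(overlaps)
  }
  pmf <- rep(0, min(n_a, n_b) + 1)
  names(pmf) <- 0:min(n_a, n_b)
  pmf[names(counts)] <- as.numeric(counts) / sum(counts)
  pmf
}

enum_tails <- function(N, n_a, n_b, j_obs) {
  pmf <- enum_pmf(N, n_a, n_b)
  j <- as.integer(names(pmf))
  list(p_lt = sum(pmf[j <= j_obs]), p_gt = sum(pmf[j >= j_obs]))
}

# O(n^2) concordant/discordant tau-b oracle
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx * sy > 0) C <- C + 1
    if (sx * sy < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# minimal community: 2 Cercozoa + 3 Bacteria over 3 sites
tiny_taxonomy <- function() {
  data.frame(
    otu_id = c("c1", "c2", "b1", "b2", "b3"),
    lineage = c("Cercozoa;GenA", "Cercozoa;GenB", "Proteobacteria;FamX",
                "Actinobacteria;FamY", "Proteobacteria;FamZ"),
    rank = c("genus", "genus", "family", "family", "family"),
    taxon = c("GenA", "GenB", "FamX", "FamY", "FamZ"),
    phylum = c("Cercozoa", "Cercozoa", "Proteobacteria", "Actinobacteria",
               "Proteobacteria"),
    functional_group = c("Cercozoa", "Cercozoa", "Bacteria", "Bacteria",
                         "Bacteria"),
    trophic_role = c("bacterivore", "bacterivore", "prey_eligible",
                     "prey_eligible", "prey_eligible"))
}

tiny_table <- function(abund = NULL) {
  if (is.null(abund)) {
    abund <- matrix(c(2, 3, 5,
                      0, 1, 4,
                      1, 0, 2,
                      3, 3, 0,
                      0, 2, 2), nrow = 3,
                    dimnames = list(paste0("s", 1:3), NULL))
  }
  otu_table(abund, tiny_taxonomy(), otu_ids = c("c1", "c2", "b1", "b2", "b3"))
}

# an assoc_set with hand-set statuses, for network/annotation tests
manual_assoc <- function(otu_a, otu_b, status) {
  out <- data.frame(otu_a = otu_a, otu_b = otu_b, n_sites = 18L,
                    n_a = 9L, n_b = 9L, j_obs = 8L, j_expected = 4.5,
                    p_lt = 0.99, p_gt = 0.01, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_set", "data.frame")
  out
}
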