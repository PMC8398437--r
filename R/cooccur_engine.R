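#' Probability mass of the randomized co-occurrence model
#'
#' Probability that two OTUs occupying `n_a` and `n_b` of `N` sites share
#' exactly `j` sites when both place their occurrences uniformly at random:
#' `C(n_a, j) * C(N - n_a, n_b - j) / C(N, n_b)` (hypergeometric form). For
#' small `N` the binomial coefficients are evaluated as exact integer-valued
#' doubles; otherwise in log space. `j` outside the feasible support returns
#' probability 0.
#'
#' @param N Number of sites.
#' @param n_a,n_b Occurrence counts of the two OTUs (0..N).
#' @param j Shared-site count (vectorized).
#' @return Probability vector, same length as `j`.
#' @export
cooccurrence_pmf <- function(N, n_a, n_b, j) {
  if (length(N) != 1 || length(n_a) != 1 || length(n_b) != 1 ||
      N %% 1 != 0 || n_a %% 1 != 0 || n_b %% 1 != 0 || any(j %% 1 != 0)) {
    stop("counts must be scalar integers (j may be a vector)")
  }
  if (N < 0 || n_a < 0 || n_b < 0 || n_a > N || n_b > N) {
    stop("invalid counts: need 0 <= n_a, n_b <= N")
  }
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  out <- numeric(length(j))
  ok <- j >= lo & j <= hi
  if (any(ok)) {
    jj <- j[ok]
    if (N <= 25) {
      out[ok] <- choose(n_a, jj) * choose(N - n_a, n_b - jj) / choose(N, n_b)
    } else {
      out[ok] <- exp(lchoose(n_a, jj) + lchoose(N - n_a, n_b - jj) -
                       lchoose(N, n_b))
    }
  }
  out
}

cooccur_tails <- function(N, n_a, n_b, j_obs) {
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  pmf <- cooccurrence_pmf(N, n_a, n_b, lo:hi)
  list(p_lt = sum(pmf[(lo:hi) <= j_obs]),
       p_gt = sum(pmf[(lo:hi) >= j_obs]))
}

classify_pair <- function(N, n_a, n_b, j_obs, alpha) {
  j_expected <- n_a * n_b / N
  if (j_expected <= 1) {
    return(list(j_expected = j_expected, p_lt = NA_real_, p_gt = NA_real_,
                status = "excluded"))
  }
  t <- cooccur_tails(N, n_a, n_b, j_obs)
  status <- if (t$p_gt < alpha) "aggregate"
  else if (t$p_lt < alpha) "segregate"
  else "random"
  list(j_expected = j_expected, p_lt = t$p_lt, p_gt = t$p_gt, status = status)
}

#' Test one OTU pair for non-random co-occurrence
#'
#' Two one-tailed exact tests against the randomized distribution model, both
#' tails inclusive of the observed count. Pairs expected to share one site or
#' fewer (`n_a*n_b/N <= 1`) are excluded from classification — low-frequency
#' OTUs cannot yield informative tails.
#'
#' @param pa A `pa_matrix` from [to_presence_absence()].
#' @param otu_a,otu_b OTU ids.
#' @param alpha Significance level for classification (strict `<`), default
#'   0.05.
#' @return One-row data frame with columns `otu_a`, `otu_b`, `n_sites`,
#'   `n_a`, `n_b`, `j_obs`, `j_expected`, `p_lt`, `p_gt`, `status`
#'   (aggregate / segregate / random / excluded).
#' @export
test_pair <- function(pa, otu_a, otu_b, alpha = 0.05) {
  stopifnot(inherits(pa, "pa_matrix"))
  for (o in c(otu_a, otu_b)) {
    if (!o %in% pa$otu_ids) stop("unknown OTU id: ", o)
  }
  N <- length(pa$site_ids)
  va <- pa$presence[, otu_a]
  vb <- pa$presence[, otu_b]
  n_a <- sum(va); n_b <- sum(vb); j_obs <- sum(va * vb)
  cl <- classify_pair(N, n_a, n_b, j_obs, alpha)
  data.frame(otu_a = otu_a, otu_b = otu_b, n_sites = N, n_a = n_a, n_b = n_b,
             j_obs = j_obs, j_expected = cl$j_expected,
             p_lt = cl$p_lt, p_gt = cl$p_gt, status = cl$status,
             stringsAsFactors = FALSE)
}

#' Test every unordered OTU pair
#'
#' No multiple-testing adjustment is applied by default (the classical
#' convention for this model); `p_adjust = "BH"` classifies on
#' Benjamini-Hochberg-adjusted tails instead, adjusted across all
#' non-excluded pairs per tail.
#'
#' @param pa A `pa_matrix`.
#' @param alpha Significance level (strict `<`).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame of class `assoc_set`, one row per unordered pair,
#'   excluded pairs retained with status `"excluded"`.
#' @export
test_all_pairs <- function(pa, alpha = 0.05, p_adjust = c("none", "BH")) {
  stopifnot(inherits(pa, "pa_matrix"))
  p_adjust <- match.arg(p_adjust)
  m <- ncol(pa$presence)
  if (m < 2) stop("need at least 2 OTUs to test pairs")
  N <- length(pa$site_ids)
  cross <- crossprod(pa$presence)           # j_obs for every pair
  counts <- pa$occurrence_count
  idx <- which(upper.tri(cross), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  n_a <- counts[a]; n_b <- counts[b]
  j_obs <- cross[idx]
  j_expected <- n_a * n_b / N
  p_lt <- rep(NA_real_, length(a))
  p_gt <- rep(NA_real_, length(a))
  todo <- which(j_expected > 1)
  # tails are cached on (n_a, n_b, j) since many pairs share margins
  cache <- new.env(hash = TRUE)
  for (k in todo) {
    key <- paste(min(n_a[k], n_b[k]), max(n_a[k], n_b[k]), j_obs[k], sep = "_")
    t <- cache[[key]]
    if (is.null(t)) {
      t <- cooccur_tails(N, n_a[k], n_b[k], j_obs[k])
      cache[[key]] <- t
    }
    p_lt[k] <- t$p_lt; p_gt[k] <- t$p_gt
  }
  p_lt_c <- p_lt; p_gt_c <- p_gt
  if (p_adjust == "BH") {
    p_lt_c[todo] <- stats::p.adjust(p_lt[todo], "BH")
    p_gt_c[todo] <- stats::p.adjust(p_gt[todo], "BH")
  }
  status <- rep("excluded", length(a))
  status[todo] <- ifelse(p_gt_c[todo] < alpha, "aggregate",
                         ifelse(p_lt_c[todo] < alpha, "segregate", "random"))
  out <- data.frame(otu_a = pa$otu_ids[a], otu_b = pa$otu_ids[b],
                    n_sites = N, n_a = n_a, n_b = n_b, j_obs = j_obs,
                    j_expected = j_expected, p_lt = p_lt, p_gt = p_gt,
                    status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("assoc_set", "data.frame")
  out
}

#' Keep only significant (aggregate/segregate) associations
#' @param associations An `assoc_set` from [test_all_pairs()].
#' @return The significant subset (plain data frame semantics preserved).
#' @export
significant_associations <- function(associations) {
  associations[associations$status %in% c("aggregate", "segregate"), ,
               drop = FALSE]
}
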