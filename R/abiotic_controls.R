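#' Assign per-site co-occurrence states for a pair
#'
#' `"11"` where both OTUs are present, `"00"` where both absent, `"10"`/`"01"`
#' where only the first/second member of the (ordered) pair is present.
#'
#' @param pa A `pa_matrix`.
#' @param otu_a,otu_b OTU ids; their order fixes which OTU the first digit
#'   refers to.
#' @return A `state_assignment` list: `pair`, `states` (per-site character
#'   vector named by site).
#' @export
assign_states <- function(pa, otu_a, otu_b) {
  stopifnot(inherits(pa, "pa_matrix"))
  for (o in c(otu_a, otu_b)) {
    if (!o %in% pa$otu_ids) stop("unknown OTU id: ", o)
  }
  st <- paste0(pa$presence[, otu_a], pa$presence[, otu_b])
  names(st) <- pa$site_ids
  structure(list(pair = c(otu_a, otu_b), states = st),
            class = "state_assignment")
}

#' Compress abiotic variables by principal components
#'
#' Standardizes every variable (zero mean, unit variance) and retains the
#' smallest number of principal components whose cumulative explained
#' variance reaches `var_target`, so the MANOVA dependent block carries as
#' much abiotic variation in as few variables as possible.
#'
#' @param abiotic An [abiotic_table()] or numeric data frame.
#' @param var_target Cumulative explained-variance target (default 0.90).
#' @return List with `scores` (site x k), `k`, `explained` (per-PC variance
#'   shares), `cumulative`.
#' @export
compress_abiotic_pca <- function(abiotic, var_target = 0.90) {
  df <- if (inherits(abiotic, "abiotic_table")) abiotic$variables else
    as.data.frame(abiotic)
  if (ncol(df) < 2) stop("need at least 2 variables")
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(names(df)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(df, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  expl <- ev / sum(ev)
  cum <- cumsum(expl)
  k <- which(cum >= var_target - 1e-12)[1]
  list(scores = pc$x[, seq_len(k), drop = FALSE], k = k,
       explained = expl, cumulative = cum)
}

#' Henze-Zirkler test of multivariate normality
#'
#' Smooth-test statistic based on the weighted L2 distance between the
#' empirical characteristic function of the scaled residuals and the
#' standard multivariate normal one; the null distribution is approximated
#' by a log-normal matched to the statistic's first two moments.
#'
#' @param x Numeric matrix (n x p), n > p required for a nonsingular
#'   covariance.
#' @return List with `HZ`, `p_value`, `n`, `p`; `p_value` is NA when the
#'   sample covariance is singular.
#' @export
henze_zirkler <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1) return(list(HZ = NA_real_, p_value = NA_real_, n = n, p = p))
  S <- stats::cov(x) * (n - 1) / n            # ML covariance
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    return(list(HZ = NA_real_, p_value = NA_real_, n = n, p = p))
  }
  xc <- sweep(x, 2, colMeans(x))
  Dj <- rowSums((xc %*% Sinv) * xc)           # squared Mahalanobis to mean
  Y <- xc %*% Sinv
  Dij <- outer(Dj, Dj, "+") - 2 * tcrossprod(Y %*% S, Y)  # pairwise sq. Mahal.
  # numeric guard: tiny negatives from cancellation
  Dij[Dij < 0] <- 0
  b <- (1 / sqrt(2)) * ((2 * p + 1) * n / 4)^(1 / (p + 4))
  HZ <- n * (mean(exp(-b^2 / 2 * Dij)) -
               2 * (1 + b^2)^(-p / 2) * mean(exp(-b^2 / (2 * (1 + b^2)) * Dj)) +
               (1 + 2 * b^2)^(-p / 2))
  a <- 1 + 2 * b^2
  wb <- (1 + b^2) * (1 + 3 * b^2)
  mu <- 1 - a^(-p / 2) * (1 + p * b^2 / a + p * (p + 2) * b^4 / (2 * a^2))
  si2 <- 2 * (1 + 4 * b^2)^(-p / 2) +
    2 * a^(-p) * (1 + 2 * p * b^4 / a^2 + 3 * p * (p + 2) * b^8 / (4 * a^4)) -
    4 * wb^(-p / 2) * (1 + 3 * p * b^4 / (2 * wb) +
                         p * (p + 2) * b^8 / (2 * wb^2))
  pmu <- log(sqrt(mu^4 / (si2 + mu^2)))
  psi <- sqrt(log((si2 + mu^2) / mu^2))
  pval <- stats::plnorm(HZ, pmu, psi, lower.tail = FALSE)
  list(HZ = HZ, p_value = pval, n = n, p = p)
}

#' One-way MANOVA of a dependent block on co-occurrence states
#'
#' Assumptions are checked first, on the data *after* partitioning by state:
#' every analyzed state group must have more sites than dependent variables,
#' and each group must pass a multivariate normality test (Henze-Zirkler by
#' default, Mardia skewness/kurtosis via `normality = "mardia"`) at
#' `alpha_assumption`. If any check fails no test statistic is reported.
#' Otherwise the states enter as a single factor and Pillai's trace with its
#' F approximation is returned.
#'
#' @param states A `state_assignment`.
#' @param dependents Site x m numeric table (geographic coordinates or
#'   abiotic principal components), rows aligned with the states.
#' @param alpha_assumption Significance level for the normality checks.
#' @param normality `"henze-zirkler"` (default) or `"mardia"`.
#' @return A `manova_result` list: `pair`, `pillai`, `F_approx`, `df1`,
#'   `df2`, `p`, `group_sizes`, `assumptions_passed`, `assumption_detail`.
#' @export
manova_pair <- function(states, dependents, alpha_assumption = 0.05,
                        normality = c("henze-zirkler", "mardia")) {
  stopifnot(inherits(states, "state_assignment"))
  normality <- match.arg(normality)
  dep <- as.matrix(dependents)
  m <- ncol(dep)
  if (m == 0) stop("no dependent variables")
  st <- states$states
  if (length(st) != nrow(dep)) stop("site mismatch between states and dependents")
  f <- factor(st)
  if (nlevels(f) < 2) stop("fewer than 2 distinct states")
  sizes <- table(f)
  detail <- data.frame(state = names(sizes), n = as.integer(sizes),
                       size_ok = as.integer(sizes) > m,
                       normality_p = NA_real_, normal_ok = NA)
  for (i in seq_len(nrow(detail))) {
    if (!detail$size_ok[i]) next
    xg <- dep[f == detail$state[i], , drop = FALSE]
    pv <- if (normality == "henze-zirkler") henze_zirkler(xg)$p_value else
      mardia_p(xg)
    detail$normality_p[i] <- pv
    detail$normal_ok[i] <- !is.na(pv) && pv > alpha_assumption
  }
  passed <- all(detail$size_ok) && all(detail$normal_ok %in% TRUE)
  res <- list(pair = states$pair, pillai = NA_real_, F_approx = NA_real_,
              df1 = NA_real_, df2 = NA_real_, p = NA_real_,
              group_sizes = sizes, assumptions_passed = passed,
              assumption_detail = detail)
  if (passed) {
    if (m == 1) {
      # univariate boundary: Pillai reduces to SSB/SST and its F to the
      # classical one-way ANOVA F
      a <- stats::anova(stats::lm(dep[, 1] ~ f))
      ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
      res$pillai <- ssb / (ssb + ssw)
      res$F_approx <- a$`F value`[1]
      res$df1 <- a$Df[1]
      res$df2 <- a$Df[2]
      res$p <- a$`Pr(>F)`[1]
    } else {
      fit <- stats::manova(dep ~ f)
      sm <- summary(fit, test = "Pillai")$stats
      res$pillai <- sm[1, "Pillai"]
      res$F_approx <- sm[1, "approx F"]
      res$df1 <- sm[1, "num Df"]
      res$df2 <- sm[1, "den Df"]
      res$p <- sm[1, "Pr(>F)"]
    }
  }
  class(res) <- "manova_result"
  res
}

# Mardia's skewness + kurtosis p-values combined conservatively (minimum);
# available as an alternative assumption check
mardia_p <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1) return(NA_real_)
  S <- stats::cov(x) * (n - 1) / n
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) return(NA_real_)
  xc <- sweep(x, 2, colMeans(x))
  D <- xc %*% Sinv %*% t(xc)
  b1 <- mean(D^3)
  b2 <- mean(diag(D)^2)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  p_skew <- stats::pchisq(skew_stat, skew_df, lower.tail = FALSE)
  kurt_stat <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  p_kurt <- 2 * stats::pnorm(abs(kurt_stat), lower.tail = FALSE)
  min(p_skew, p_kurt)
}

#' @export
print.manova_result <- function(x, ...) {
  cat("<manova_result> pair ", paste(x$pair, collapse = " ~ "), ": ", sep = "")
  if (x$assumptions_passed) {
    cat(sprintf("Pillai = %.4f, F(%g, %g) = %.3f, p = %.4f\n",
                x$pillai, x$df1, x$df2, x$F_approx, x$p))
  } else cat("assumptions not met; no statistic reported\n")
  invisible(x)
}

#' Control one association for abiotic filtering and dispersal limitation
#'
#' Runs two MANOVAs over the pair's co-occurrence states — one against
#' geographic coordinates (dispersal), one against compressed abiotic PCs
#' (habitat filtering). Verdict: `"biotic"` when both were analyzable and
#' both p > 0.05; `"abiotic_or_dispersal"` when any analyzable test rejects
#' at 0.05; `"untestable"` when assumptions failed.
#'
#' @param assoc One-row association record with status aggregate/segregate.
#' @param pa The `pa_matrix`.
#' @param abiotic An [abiotic_table()] (must carry coordinates unless
#'   `coords` is given).
#' @param coords Optional site x 2 coordinate matrix.
#' @param var_target PCA variance target for the abiotic block.
#' @return List with `geo` and `abiotic` (`manova_result`s) and `verdict`.
#' @export
control_association <- function(assoc, pa, abiotic, coords = NULL,
                                var_target = 0.90) {
  if (!assoc$status %in% c("aggregate", "segregate")) {
    stop("association must be classified aggregate or segregate")
  }
  if (is.null(coords)) coords <- abiotic$coordinates
  if (is.null(coords)) stop("no geographic coordinates available")
  st <- assign_states(pa, assoc$otu_a, assoc$otu_b)
  pcs <- compress_abiotic_pca(abiotic, var_target = var_target)$scores
  res_geo <- tryCatch(manova_pair(st, coords), error = function(e) NULL)
  res_abi <- tryCatch(manova_pair(st, pcs), error = function(e) NULL)
  analyzable <- function(r) !is.null(r) && r$assumptions_passed
  verdict <- if (analyzable(res_geo) && analyzable(res_abi)) {
    if (res_geo$p > 0.05 && res_abi$p > 0.05) "biotic" else "abiotic_or_dispersal"
  } else if ((analyzable(res_geo) && res_geo$p <= 0.05) ||
             (analyzable(res_abi) && res_abi$p <= 0.05)) {
    "abiotic_or_dispersal"
  } else "untestable"
  list(geo = res_geo, abiotic = res_abi, verdict = verdict)
}
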