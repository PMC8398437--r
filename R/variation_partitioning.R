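#' Screen abiotic variables for collinearity
#'
#' Greedy exclusion on pairwise Pearson correlations: offending pairs
#' (`|r| > r_max`) are visited in descending `|r|`; within a pair the variable
#' with the larger mean absolute correlation to all other variables is
#' dropped (tie broken toward the later column). Repeats until no retained
#' pair exceeds the threshold. Variance inflation factors for the retained
#' set are computed from the inverse correlation matrix.
#'
#' @param abiotic An [abiotic_table()] (or plain numeric data frame).
#' @param r_max Exclusion threshold on `|r|` (default 0.70; strictly above
#'   the threshold triggers exclusion).
#' @return A `collinearity_report` list: `pearson_matrix`,
#'   `excluded_variables` (data frame variable/trigger/r), `retained`,
#'   `vif_table`, `variables` (the screened numeric data frame).
#' @export
screen_collinearity <- function(abiotic, r_max = 0.70) {
  df <- if (inherits(abiotic, "abiotic_table")) abiotic$variables else
    as.data.frame(abiotic)
  if (ncol(df) < 2) stop("need at least 2 numeric variables")
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant column(s), correlation undefined: ",
         paste(names(df)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(df)
  keep <- names(df)
  dropped <- list()
  repeat {
    sub <- R[keep, keep, drop = FALSE]
    off <- which(abs(sub) > r_max & upper.tri(sub), arr.ind = TRUE)
    if (!nrow(off)) break
    off <- off[order(-abs(sub[off])), , drop = FALSE]
    i <- keep[off[1, 1]]; j <- keep[off[1, 2]]
    mean_abs <- function(v) mean(abs(sub[v, setdiff(keep, v)]))
    drop_var <- if (mean_abs(i) > mean_abs(j)) i
    else if (mean_abs(j) > mean_abs(i)) j
    else keep[max(match(c(i, j), keep))]   # tie: later column order
    dropped[[length(dropped) + 1]] <- data.frame(
      variable = drop_var, trigger = setdiff(c(i, j), drop_var),
      r = sub[i, j])
    keep <- setdiff(keep, drop_var)
  }
  excluded <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(variable = character(), trigger = character(), r = numeric())
  Rk <- R[keep, keep, drop = FALSE]
  vif <- diag(solve(Rk))
  structure(list(pearson_matrix = R, excluded_variables = excluded,
                 retained = keep,
                 vif_table = data.frame(variable = keep, vif = unname(vif)),
                 variables = df[, keep, drop = FALSE]),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("<collinearity_report> retained ", length(x$retained), " variables; ",
      nrow(x$excluded_variables), " excluded; max VIF ",
      signif(max(x$vif_table$vif), 3), "\n", sep = "")
  invisible(x)
}

#' Two-block NIPALS partial least squares
#'
#' Regression-mode PLS2: X scores are extracted by the classic NIPALS
#' iteration, X is deflated by its rank-one reconstruction after each
#' component (scores therefore mutually orthogonal), Y is deflated by its
#' regression on the X score. Columns of both blocks are mean-centered.
#'
#' @param X Predictor matrix (n x p).
#' @param Y Response matrix (n x q).
#' @param ncomp Number of components.
#' @param tol,maxit NIPALS convergence control.
#' @return List with `scores` (n x ncomp X-scores), `loadings`, `weights`,
#'   `cov_share` (per-component share of score covariance, see
#'   [build_biotic_component()]).
#' @keywords internal
nipals_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  n <- nrow(X)
  scores <- matrix(0, n, ncomp)
  loadings <- matrix(0, ncol(X), ncomp)
  weights <- matrix(0, ncol(X), ncomp)
  covs <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (all(abs(u) < .Machine$double.eps)) break
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      t_ <- X %*% w
      q <- crossprod(Y, t_); q <- q / sqrt(sum(q^2))
      u <- Y %*% q
      if (sqrt(sum((t_ - t_old)^2)) < tol * sqrt(sum(t_^2))) break
      t_old <- t_
    }
    p <- crossprod(X, t_) / sum(t_^2)
    covs[h] <- abs(stats::cov(t_, u))
    scores[, h] <- t_
    loadings[, h] <- p
    weights[, h] <- w
    X <- X - tcrossprod(t_, p)
    b <- crossprod(t_, Y) / sum(t_^2)
    Y <- Y - t_ %*% b
  }
  list(scores = scores, loadings = loadings, weights = weights, covs = covs)
}

#' Build a biotic explanatory component by PLS
#'
#' Compresses one biotic group's presence/absence matrix into a few latent
#' scores that covary maximally with the protist response abundances, so
#' large biotic blocks never enter the partition with one predictor per OTU.
#' Retained components: at least the first two, extended until the cumulative
#' covariance share reaches `share_target`, capped at
#' `min(n_sites - 1, n_predictors)`. With `strict_two = TRUE` exactly two
#' components (subject to the cap) are retained instead.
#'
#' @param response Site x OTU response abundance matrix.
#' @param predictor_pa Site x OTU presence matrix of one biotic group.
#' @param share_target Cumulative covariance share to reach (default 0.5).
#' @param strict_two Retain exactly `min(2, cap)` components.
#' @return A `biotic_component` list: `scores` (site x k), `k`,
#'   `covariance_share` (cumulative share at k), `shares` (per component).
#' @export
build_biotic_component <- function(response, predictor_pa, share_target = 0.5,
                                   strict_two = FALSE) {
  response <- as.matrix(response)
  predictor_pa <- as.matrix(predictor_pa)
  if (ncol(predictor_pa) == 0) stop("empty predictor group")
  n <- nrow(response)
  if (n < 3) stop("need at least 3 sites")
  if (nrow(predictor_pa) != n) stop("site mismatch between blocks")
  cap <- min(n - 1, ncol(predictor_pa))
  fit <- nipals_pls(predictor_pa, response, ncomp = cap)
  shares <- if (sum(fit$covs) > 0) fit$covs / sum(fit$covs) else
    rep(0, length(fit$covs))
  cum <- cumsum(shares)
  k <- if (strict_two) min(2, cap) else
    min(max(2, which(cum >= share_target)[1]), cap)
  structure(list(scores = fit$scores[, seq_len(k), drop = FALSE], k = k,
                 covariance_share = cum[k], shares = shares),
            class = "biotic_component")
}

rda_fit <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qr_x <- qr(X)
  p <- qr_x$rank
  fitted <- qr.fitted(qr_x, Y)
  ss_tot <- sum(Y^2)
  ss_fit <- sum(fitted^2)
  list(R2 = ss_fit / ss_tot, rank = p, fitted = fitted,
       resid = Y - fitted, ss_tot = ss_tot, ss_fit = ss_fit)
}

#' Redundancy-analysis R-squared of a multivariate response
#'
#' Multivariate least squares of the centered response on the explanatory
#' block; `R2` is the trace of the fitted sum of squares over the total sum
#' of squares (the constrained fraction of an RDA). The adjustment is
#' Ezekiel's, using the rank of the centered explanatory block (not its
#' column count), and may legitimately be negative.
#'
#' @param Y Site x variable response matrix.
#' @param X Site x variable explanatory matrix.
#' @return List with `R2`, `R2adj` (NA with a warning when `n <= rank + 1`),
#'   `rank`.
#' @export
rda_r2 <- function(Y, X) {
  f <- rda_fit(Y, X)
  n <- nrow(as.matrix(Y))
  R2adj <- if (n > f$rank + 1) {
    1 - (1 - f$R2) * (n - 1) / (n - f$rank - 1)
  } else {
    warning("adjustment undefined: n <= rank + 1")
    NA_real_
  }
  list(R2 = f$R2, R2adj = R2adj, rank = f$rank)
}

# pseudo-F for Y ~ X (optionally partialling out Z): constrained df uses
# matrix rank, residual df the rank of the combined model
rda_F <- function(Y, X, Z = NULL) {
  n <- nrow(as.matrix(Y))
  if (is.null(Z)) {
    f <- rda_fit(Y, X)
    df1 <- f$rank
    df2 <- n - f$rank - 1
    ss_x <- f$ss_fit
    ss_res <- f$ss_tot - f$ss_fit
  } else {
    fz <- rda_fit(Y, Z)
    fxz <- rda_fit(Y, cbind(as.matrix(X), as.matrix(Z)))
    df1 <- fxz$rank - fz$rank
    df2 <- n - fxz$rank - 1
    ss_x <- fxz$ss_fit - fz$ss_fit
    ss_res <- fxz$ss_tot - fxz$ss_fit
  }
  if (df1 <= 0 || df2 <= 0) return(list(F = NA_real_, df1 = df1, df2 = df2))
  list(F = (ss_x / df1) / (ss_res / df2), df1 = df1, df2 = df2)
}

perm_p <- function(F_obs, F_perm) {
  (sum(F_perm >= F_obs, na.rm = TRUE) + 1) / (sum(!is.na(F_perm)) + 1)
}

#' Partition response variation into abiotic, shared, biotic and residual
#'
#' Three-model decomposition on adjusted R-squared: with `ab` the abiotic
#' block, `bi` the biotic block and `full` their union,
#' `a = R2adj(full) - R2adj(bi)` (abiotic-only),
#' `c = R2adj(full) - R2adj(ab)` (biotic-only),
#' `b = R2adj(ab) + R2adj(bi) - R2adj(full)` (shared) and
#' `d = 1 - R2adj(full)`; the four sum to 1 by construction and negative
#' adjusted fractions are reported as computed. Significance: full-model
#' fractions (`ab` = a+b, `bc` = b+c) by free permutation of the response's
#' site rows; unique fractions (a, c) by residual permutation under the
#' reduced model (the other block).
#'
#' @param Y Site x OTU response abundances.
#' @param X_abiotic Screened abiotic explanatory matrix.
#' @param X_biotic Biotic explanatory matrix (e.g. PLS scores); may have zero
#'   columns, collapsing to a single-block RDA.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A `varpart_result` list: `fractions` (a, b, c, d), `R2adj` of the
#'   three models, `tests` data frame (fraction, F, df1, df2, p_perm),
#'   `n_perm`.
#' @export
partition_variation <- function(Y, X_abiotic, X_biotic, n_perm = 999,
                                seed = 1L) {
  Y <- as.matrix(Y)
  Xa <- as.matrix(X_abiotic)
  Xb <- as.matrix(X_biotic)
  n <- nrow(Y)
  if ((ncol(Xa) && nrow(Xa) != n) || (ncol(Xb) && nrow(Xb) != n)) {
    stop("site mismatch between response and explanatory matrices")
  }
  empty_bi <- ncol(Xb) == 0
  r_ab <- rda_r2(Y, Xa)
  r_bi <- if (empty_bi) list(R2 = 0, R2adj = 0, rank = 0) else rda_r2(Y, Xb)
  r_full <- if (empty_bi) r_ab else rda_r2(Y, cbind(Xa, Xb))
  a <- r_full$R2adj - r_bi$R2adj
  c_ <- r_full$R2adj - r_ab$R2adj
  b <- r_ab$R2adj + r_bi$R2adj - r_full$R2adj
  d <- 1 - r_full$R2adj

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)

  run_test <- function(X, Z = NULL) {
    obs <- rda_F(Y, X, Z)
    if (is.na(obs$F)) return(c(obs, list(p = NA_real_)))
    fz <- if (!is.null(Z)) rda_fit(Y, Z)
    Fp <- vapply(perms, function(pm) {
      if (is.null(Z)) {
        rda_F(Y[pm, , drop = FALSE], X)$F
      } else {
        # ter Braak residual permutation under the reduced model
        Yp <- fz$fitted + fz$resid[pm, , drop = FALSE]
        rda_F(Yp, X, Z)$F
      }
    }, numeric(1))
    c(obs, list(p = perm_p(obs$F, Fp)))
  }

  tests <- list(ab = run_test(Xa))
  if (!empty_bi) {
    tests$bc <- run_test(Xb)
    tests$a <- run_test(Xa, Z = Xb)
    tests$c <- run_test(Xb, Z = Xa)
  }
  tests_df <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(fraction = nm, F = t$F, df1 = t$df1, df2 = t$df2, p_perm = t$p)
  }))
  structure(list(fractions = c(a = a, b = if (empty_bi) 0 else b,
                               c = if (empty_bi) 0 else c_, d = d),
                 R2adj = c(abiotic = r_ab$R2adj, biotic = r_bi$R2adj,
                           full = r_full$R2adj),
                 tests = tests_df, n_perm = n_perm),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  fr <- signif(x$fractions, 3)
  cat("<varpart_result> a=", fr["a"], " b=", fr["b"], " c=", fr["c"],
      " d=", fr["d"], " (", x$n_perm, " permutations)\n", sep = "")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Run the full variation-partitioning suite
#'
#' For each response guild: one run with all biota (minus the guild itself)
#' as the biotic block, plus one run per other single biotic grouping —
#' 10 subgroup runs per guild when all eleven groupings are present, i.e. 50
#' planned subgroup tests for the five guilds. Response groups absent from
#' the table are skipped with a logged reason.
#'
#' @param table Normalized [otu_table()].
#' @param abiotic An [abiotic_table()]; the collinearity screen is applied
#'   here (`r_max`).
#' @param response_groups Guild labels (default [protist_guilds()]).
#' @param biotic_groupings Single-group labels (default all eleven of
#'   [functional_groups()]).
#' @param n_perm,seed Permutation control.
#' @param r_max Collinearity threshold for the abiotic screen.
#' @param pa_threshold Presence threshold for predictor matrices.
#' @return A `varpart_suite` list: `runs` (named list of `varpart_result`),
#'   `plan` data frame (response, biotic grouping, status), `screen` (the
#'   `collinearity_report`).
#' @export
run_varpart_suite <- function(table, abiotic,
                              response_groups = protist_guilds(),
                              biotic_groupings = functional_groups(),
                              n_perm = 999, seed = 1L, r_max = 0.70,
                              pa_threshold = 0) {
  stopifnot(inherits(table, "otu_table"))
  bad <- setdiff(c(response_groups, biotic_groupings), functional_groups())
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  screen <- screen_collinearity(abiotic, r_max = r_max)
  Xa <- as.matrix(screen$variables)
  pa <- to_presence_absence(table, threshold = pa_threshold)
  runs <- list(); plan <- list()
  ri <- 0L
  for (resp in response_groups) {
    Yt <- select_group(table, resp)
    if (length(Yt$otu_ids) == 0) {
      plan[[length(plan) + 1]] <- data.frame(
        response = resp, biotic = NA_character_, status = "skipped_empty_response")
      next
    }
    Y <- Yt$abundance
    for (bio in c("all_biota", setdiff(biotic_groupings, resp))) {
      ri <- ri + 1L
      pred <- select_group(table, bio, response_group = resp)
      key <- paste(resp, bio, sep = "~")
      if (length(pred$otu_ids) == 0) {
        plan[[length(plan) + 1]] <- data.frame(
          response = resp, biotic = bio, status = "skipped_empty_predictor")
        next
      }
      Xp <- pa$presence[, pred$otu_ids, drop = FALSE]
      bc <- build_biotic_component(Y, Xp)
      runs[[key]] <- partition_variation(Y, Xa, bc$scores, n_perm = n_perm,
                                         seed = seed + ri)
      runs[[key]]$response_group <- resp
      runs[[key]]$biotic_grouping <- bio
      runs[[key]]$pls_k <- bc$k
      plan[[length(plan) + 1]] <- data.frame(response = resp, biotic = bio,
                                             status = "run")
    }
  }
  structure(list(runs = runs, plan = do.call(rbind, plan), screen = screen),
            class = "varpart_suite")
}
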