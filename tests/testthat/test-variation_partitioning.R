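test_that("collinearity screen drops greedily and reports triggers", {
  set.seed(1)
  base <- rnorm(20)
  df <- data.frame(v1 = base, v2 = base, v3 = rnorm(20))
  rep_ <- screen_collinearity(df)
  expect_equal(nrow(rep_$excluded_variables), 1)  # identical pair: one dropped
  expect_equal(length(rep_$retained), 2)

  # sample r just under the threshold: both retained
  e <- residuals(lm(rnorm(20) ~ base)); e <- e / sd(e)
  df2 <- data.frame(v1 = base, v2 = scale(base)[, 1] * 0.69 + sqrt(1 - 0.69^2) * e)
  expect_equal(abs(cor(df2$v1, df2$v2)), 0.69, tolerance = 1e-10)
  rep2 <- screen_collinearity(df2)
  expect_equal(length(rep2$retained), 2)

  # three mutually collinear columns: exactly two dropped
  df3 <- data.frame(a = base, b = base + rnorm(20, 0, 0.05),
                    c = base + rnorm(20, 0, 0.05), d = rnorm(20))
  stopifnot(all(abs(cor(df3[, 1:3])[upper.tri(diag(3))]) > 0.9))
  rep3 <- screen_collinearity(df3)
  expect_equal(nrow(rep3$excluded_variables), 2)
  expect_true("d" %in% rep3$retained)
  # retained set is clean and VIFs are finite
  R <- cor(rep3$variables)
  expect_lt(max(abs(R[upper.tri(R)])), 0.70 + 1e-12)
  expect_true(all(is.finite(rep3$vif_table$vif)))

  expect_error(screen_collinearity(data.frame(a = rep(1, 5), b = rnorm(5))),
               "constant")
})

test_that("PLS scores match an independent NIPALS implementation", {
  # oracle: mixOmics NIPALS (regression mode, centered, unscaled); scores
  # agree columnwise up to sign
  skip_if_not_installed("mixOmics")
  set.seed(3)
  X <- matrix(rbinom(18, 1, 0.5), 6, 3)
  Y <- matrix(rnorm(24), 6, 4)
  fit <- phagonet:::nipals_pls(X, Y, ncomp = 2)
  mo <- suppressMessages(mixOmics::pls(X, Y, ncomp = 2, mode = "regression",
                                       scale = FALSE))
  for (h in 1:2) {
    d <- min(max(abs(fit$scores[, h] - mo$variates$X[, h])),
             max(abs(fit$scores[, h] + mo$variates$X[, h])))
    expect_lt(d, 1e-8)
  }
})

test_that("biotic component retention follows the floor/share/cap rules", {
  set.seed(4)
  n <- 12
  # one latent factor drives predictor and response alike: the first
  # component captures nearly all covariance, the floor still retains two
  t1 <- rnorm(n)
  X <- outer(t1, rnorm(5)) + matrix(rnorm(n * 5, 0, 0.01), n, 5)
  bc <- build_biotic_component(X, X)
  expect_equal(bc$k, 2)
  expect_gt(bc$shares[1], 0.9)
  # single-predictor group: capped at 1
  bc1 <- build_biotic_component(matrix(rnorm(n * 3), n, 3),
                                matrix(rbinom(n, 1, 0.5), n, 1))
  expect_equal(bc1$k, 1)
  # scores mutually orthogonal
  Y <- matrix(rnorm(n * 4), n, 4)
  P <- matrix(rbinom(n * 8, 1, 0.5), n, 8)
  bc2 <- build_biotic_component(Y, P, share_target = 0.99)
  G <- crossprod(bc2$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_error(build_biotic_component(Y, P[, 0]), "empty predictor")
  expect_error(build_biotic_component(Y[1:2, ], P[1:2, ]), "3 sites")
})

test_that("rda_r2 reproduces closed forms and a normal-equations oracle", {
  set.seed(5)
  n <- 8
  X <- matrix(rnorm(n * 2), n, 2)
  B <- matrix(rnorm(2 * 2), 2, 2)
  expect_equal(rda_r2(X %*% B, X)$R2, 1, tolerance = 1e-10)

  Y <- matrix(rnorm(n * 2), n, 2)
  r <- rda_r2(Y, X)
  # oracle: explicit normal equations on centered blocks
  Yc <- scale(Y, scale = FALSE); Xc <- scale(X, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  R2o <- sum((H %*% Yc)^2) / sum(Yc^2)
  expect_equal(r$R2, R2o, tolerance = 1e-10)
  expect_equal(r$R2adj, 1 - (1 - R2o) * (n - 1) / (n - 2 - 1), tolerance = 1e-10)

  # univariate case equals classic multiple-regression R^2
  y1 <- Y[, 1]
  expect_equal(rda_r2(matrix(y1), X)$R2,
               summary(lm(y1 ~ X))$r.squared, tolerance = 1e-12)

  # in-sample orthogonal predictor: R2 = 0 and the Ezekiel adjustment < 0
  e <- residuals(lm(rnorm(n) ~ Yc[, 1] + Yc[, 2]))
  r0 <- rda_r2(Yc, matrix(e))
  expect_equal(r0$R2, 0, tolerance = 1e-10)
  expect_lt(r0$R2adj, 0)

  # rank, not column count: duplicated column changes nothing
  r2 <- rda_r2(Y, cbind(X, X[, 1]))
  expect_equal(r2$rank, 2)
  expect_equal(r2$R2adj, r$R2adj, tolerance = 1e-12)
})

test_that("rda_r2 and fractions agree with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(6)
  Y <- matrix(rnorm(30), 10, 3)
  Xa <- matrix(rnorm(20), 10, 2)
  Xb <- matrix(rnorm(20), 10, 2)
  r <- rda_r2(Y, Xa)
  v <- vegan::RsquareAdj(vegan::rda(Y ~ Xa))
  expect_equal(r$R2, v$r.squared, tolerance = 1e-10)
  expect_equal(r$R2adj, v$adj.r.squared, tolerance = 1e-10)
  vp <- partition_variation(Y, Xa, Xb, n_perm = 19, seed = 1)
  vv <- vegan::varpart(Y, Xa, Xb)$part$indfract$Adj.R.squared
  expect_equal(unname(vp$fractions[c("a", "b", "c", "d")]),
               vv[c(1, 3, 2, 4)], tolerance = 1e-10)
})

test_that("fractions sum to one and collapse correctly without a biotic block", {
  set.seed(7)
  for (i in 1:10) {
    Y <- matrix(rnorm(18 * 4), 18, 4)
    Xa <- matrix(rnorm(18 * 3), 18, 3)
    Xb <- matrix(rnorm(18 * 2), 18, 2)
    vp <- partition_variation(Y, Xa, Xb, n_perm = 9, seed = i)
    expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  }
  vp0 <- partition_variation(Y, Xa, Xb[, 0], n_perm = 9, seed = 1)
  expect_equal(unname(vp0$fractions["b"]), 0)
  expect_equal(unname(vp0$fractions["c"]), 0)
  expect_equal(unname(vp0$fractions["a"]), rda_r2(Y, Xa)$R2adj,
               tolerance = 1e-12)
  expect_error(partition_variation(Y[1:5, ], Xa, Xb), "site mismatch")
})

test_that("a planted abiotic driver yields significant a and null c", {
  # one strong gradient drives Y; the biotic block is independent noise
  set.seed(8)
  hits_a <- 0; hits_c <- 0; n_rep <- 30
  for (i in 1:n_rep) {
    n <- 18
    g <- rnorm(n)
    Y <- outer(g, c(1, -0.8, 0.6)) + matrix(rnorm(n * 3, 0, 0.4), n, 3)
    Xa <- cbind(g + rnorm(n, 0, 0.2), rnorm(n))
    Xb <- matrix(rnorm(n * 2), n, 2)
    vp <- partition_variation(Y, Xa, Xb, n_perm = 99, seed = i)
    t <- vp$tests
    hits_a <- hits_a + (t$p_perm[t$fraction == "a"] <= 0.05)
    hits_c <- hits_c + (t$p_perm[t$fraction == "c"] <= 0.05)
  }
  expect_gte(hits_a / n_rep, 0.9)
  expect_lte(hits_c / n_rep, 0.2)
})

test_that("strong-effect permutation p stays significant across seeds", {
  set.seed(9)
  n <- 18
  g <- rnorm(n)
  Y <- outer(g, c(1, -1, 0.5)) + matrix(rnorm(n * 3, 0, 0.3), n, 3)
  Xa <- cbind(g + rnorm(n, 0, 0.1))
  ps <- vapply(1:20, function(s) {
    vp <- partition_variation(Y, Xa, matrix(rnorm(n), n, 1),
                              n_perm = 99, seed = s)
    vp$tests$p_perm[vp$tests$fraction == "ab"]
  }, numeric(1))
  expect_true(all(ps <= 0.05))
})

test_that("the suite planner enumerates 50 subgroup runs plus all-biota", {
  comm <- generate_community(mdv_like_preset(seed = 2))
  tab <- normalize_total_counts(comm$table)
  suite <- run_varpart_suite(tab, comm$abiotic, n_perm = 9, seed = 1)
  plan <- suite$plan
  ran <- plan[plan$status == "run", ]
  expect_equal(sum(ran$biotic == "all_biota"), 5)
  expect_equal(sum(ran$biotic != "all_biota"), 50)
  expect_false(any(ran$response == ran$biotic))
  for (r in suite$runs) expect_equal(sum(r$fractions), 1, tolerance = 1e-10)

  # a response group absent from the table is skipped, others unaffected
  sub <- comm$table
  keep <- sub$taxonomy$functional_group != "Discoba"
  tab2 <- otu_table(sub$abundance[, keep], sub$taxonomy[keep, ])
  tab2 <- normalize_total_counts(tab2)
  suite2 <- run_varpart_suite(tab2, comm$abiotic,
                              response_groups = c("Discoba", "Cercozoa"),
                              n_perm = 9, seed = 1)
  expect_true("skipped_empty_response" %in% suite2$plan$status)
  expect_true(any(grepl("^Cercozoa~", names(suite2$runs))))
})
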