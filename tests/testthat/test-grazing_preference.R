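test_that("palatability scoring is additive over the three traits", {
  expect_equal(palatability_score(1, 1, 1), 3L)
  expect_equal(palatability_score(0, 0, 0), 0L)
  expect_equal(palatability_score(1, 0, 0), 1L)
  # flipping any single trait changes the score by exactly 1
  for (i in 1:3) {
    base <- c(0, 0, 0); flip <- base; flip[i] <- 1
    expect_equal(palatability_score(flip[1], flip[2], flip[3]) -
                   palatability_score(base[1], base[2], base[3]), 1L)
  }
  expect_error(palatability_score(NA, 1, 0), "missing")
  expect_error(palatability_score(2, 0, 0), "0/1")
})

test_that("family copy-number estimates aggregate genera and set statuses", {
  db <- data.frame(genus = c("g1", "g2", "g3", "g4"),
                   copy_number = c(2, 4, 9, 1))
  memb <- data.frame(family = c("F1", "F1", "F2", "F2", "F2"),
                     genus = c("g1", "g2", "g1", "g3", "g4"))
  e1 <- estimate_family_copy_number(db, memb, "F1")
  expect_equal(e1$mean, 3); expect_equal(e1$median, 3)
  expect_equal(e1$status, "ok")
  # genera [1, 2, 9] -> mean 4, median 2
  e2 <- estimate_family_copy_number(db, memb, "F2")
  expect_equal(e2$mean, 4); expect_equal(e2$median, 2)
  e3 <- estimate_family_copy_number(db, memb, "F9")
  expect_equal(e3$status, "excluded_not_in_db")
  e4 <- estimate_family_copy_number(db, memb, "F1", rank = "class")
  expect_equal(e4$status, "excluded_rank_above_family")
})

test_that("the chart counts richness per sign and conserves families", {
  tab <- tiny_table()
  assoc <- manual_assoc(c("c1", "c2", "c1"), c("b1", "b1", "b2"),
                        c("aggregate", "aggregate", "segregate"))
  traits <- data.frame(family = c("FamX", "FamY", "FamZ"),
                       gram_negative = c(1, 0, 1), diazotroph = c(1, 0, 0),
                       phototroph = c(0, 0, 0))
  db <- data.frame(genus = c("gx1", "gx2", "gz1"), copy_number = c(3, 5, 2))
  memb <- data.frame(family = c("FamX", "FamX", "FamZ"),
                     genus = c("gx1", "gx2", "gz1"))
  pc <- build_palatability_chart(assoc, tab, traits, db, memb)
  # FamX charted (2 protist genera, 1 phylum, aggregate); FamY not in db
  expect_equal(nrow(pc$chart), 1)
  fx <- pc$chart[pc$chart$family == "FamX", ]
  expect_equal(fx$score, 2L)
  expect_equal(fx$copy_number_mean, 4)
  expect_equal(fx$richness_genus_aggregate, 2)
  expect_equal(fx$richness_phylum_aggregate, 1)
  expect_equal(fx$richness_genus_segregate, 0)
  expect_equal(pc$excluded$reason[pc$excluded$family == "FamY"],
               "excluded_not_in_db")
  # conservation: charted + excluded = distinct bacterial families in
  # protist associations
  fams <- unique(c(pc$chart$family, pc$excluded$family))
  expect_setequal(fams, c("FamX", "FamY"))
})

test_that("rank-above-family OTUs are excluded from the chart but logged", {
  tax <- tiny_taxonomy()
  tax$rank[3] <- "class"; tax$taxon[3] <- "ud_class"
  tab <- otu_table(tiny_table()$abundance, tax,
                   otu_ids = c("c1", "c2", "b1", "b2", "b3"))
  assoc <- manual_assoc("c1", "b1", "aggregate")
  pc <- build_palatability_chart(assoc, tab,
                                 data.frame(family = "ud_class",
                                            gram_negative = 1, diazotroph = 0,
                                            phototroph = 0),
                                 data.frame(genus = "g", copy_number = 2),
                                 data.frame(family = "ud_class", genus = "g"))
  expect_equal(nrow(pc$chart), 0)
  expect_equal(pc$excluded$reason, "excluded_rank_above_family")
})

test_that("tau-b matches the brute-force oracle on a 1000-draw battery", {
  expect_equal(kendall_tau_b(1:5, 2 * (1:5)), 1)
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               brute_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3)), tolerance = 1e-12)
  expect_warning(t0 <- kendall_tau_b(1:4, rep(1, 4)), "constant")
  expect_true(is.na(t0))
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties likely
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y), brute_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("tau-b agrees with the standard correlation routine", {
  set.seed(32)
  for (i in 1:25) {
    x <- sample(1:6, 9, replace = TRUE)
    y <- sample(1:6, 9, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y), unname(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-values are sane and match no-tie references", {
  # perfectly monotone, n = 4: only the 2 extreme orderings of 24 reach |S|
  r <- kendall_tau_b_test(1:4, 1:4)
  expect_equal(r$method, "exact_permutation")
  expect_equal(r$p_value, 2 / 24, tolerance = 1e-12)
  # matches cor.test's exact two-sided p when there are no ties
  set.seed(33)
  for (i in 1:10) {
    x <- sample(1:50, 7); y <- sample(1:50, 7)
    mine <- kendall_tau_b_test(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "kendall", exact = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  # large-n branch switches to the tie-corrected normal approximation
  set.seed(34)
  x <- sample(1:5, 40, replace = TRUE); y <- sample(1:5, 40, replace = TRUE)
  big <- kendall_tau_b_test(x, y)
  expect_equal(big$method, "normal_approximation")
  ref <- suppressWarnings(cor.test(x, y, method = "kendall"))
  expect_equal(big$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("richness correlations recover a planted preference signal", {
  # segregated families planted with low palatability/copy numbers,
  # aggregated with high: tau-b for segregates should come out negative
  set.seed(35)
  sign_correct <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    n_fam <- 40
    score <- sample(0:3, n_fam, replace = TRUE)
    cn <- pmax(1, pmin(9, round(1 + score * 1.5 + rnorm(n_fam, 0, 0.8))))
    rich_seg <- rpois(n_fam, lambda = pmax(0.2, 3 - 0.8 * cn)) + 1
    chart <- data.frame(family = sprintf("f%02d", 1:n_fam), score = score,
                        copy_number_mean = cn, copy_number_median = cn,
                        richness_genus_aggregate = 0,
                        richness_genus_segregate = rich_seg,
                        richness_phylum_aggregate = 0,
                        richness_phylum_segregate = rich_seg)
    pc <- structure(list(chart = chart, associated_protists = data.frame(),
                         excluded = data.frame()),
                    class = "palatability_chart")
    res <- correlate_richness(pc, "genus", "segregate", "copy_number_mean")
    sign_correct <- sign_correct + (res$tau_b < 0)
  }
  expect_gte(sign_correct / reps, 0.95)
})

test_that("interaction inference applies the trophic rules", {
  tax <- tiny_taxonomy()
  tax$trophic_role <- c("bacterivore", "cytophage", "prey_eligible",
                        "prey_eligible", "")
  tab <- otu_table(tiny_table()$abundance, tax,
                   otu_ids = c("c1", "c2", "b1", "b2", "b3"))
  assoc <- manual_assoc(c("c1", "c2", "c1", "c1"),
                        c("b1", "c1", "c2", "b3"),
                        c("aggregate", "aggregate", "segregate", "aggregate"))
  out <- infer_interactions(assoc, tab)
  ann <- out$annotations
  # bacterivore + bacteria, aggregate -> trophic candidate
  expect_equal(ann$annotation[ann$otu_a == "c1" & ann$otu_b == "b1"],
               "trophic_candidate")
  # cytophage + protist, aggregate -> trophic candidate
  expect_equal(ann$annotation[ann$otu_a == "c2" & ann$otu_b == "c1"],
               "trophic_candidate")
  # missing role -> skipped and logged
  expect_equal(nrow(out$skipped), 1)
  expect_equal(out$skipped$otu_b, "b3")

  # segregate between two bacterivores -> competitive exclusion;
  # aggregate between two bacterivores -> no annotation
  tax2 <- tiny_taxonomy()
  tab2 <- otu_table(tiny_table()$abundance, tax2,
                    otu_ids = c("c1", "c2", "b1", "b2", "b3"))
  assoc2 <- manual_assoc(c("c1", "c1"), c("c2", "c2"),
                         c("segregate", "aggregate"))
  out2a <- infer_interactions(assoc2[1, ], tab2)
  expect_equal(out2a$annotations$annotation, "competitive_exclusion_candidate")
  out2b <- infer_interactions(assoc2[2, ], tab2)
  expect_equal(nrow(out2b$annotations), 0)
})
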