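test_that("label_inhibitors applies the 50% threshold and LQT union", {
  tab <- tibble::tibble(
    drug_id = c("exact50", "below", "both", "onlyLow", "neg"),
    pct_inhib_1uM = c(NA, NA, 40, 12, NA),
    pct_inhib_10uM = c(50, 49.9, 90, NA, 3))
  ann <- label_inhibitors(tab, lqt_list = c("both", "lqtOnly"),
                          all_drugs = c(tab$drug_id, "lqtOnly", "never"))
  lab <- setNames(ann$label, ann$drug_id)
  cls <- setNames(ann$class, ann$drug_id)
  expect_equal(lab[["exact50"]], "inhibitor")   # >= threshold, boundary in
  expect_equal(cls[["exact50"]], "experimental")
  expect_equal(lab[["below"]], "negative")
  expect_equal(cls[["both"]], "experimental")   # experimental beats lqt
  expect_equal(lab[["lqtOnly"]], "inhibitor")
  expect_equal(cls[["lqtOnly"]], "lqt")
  expect_equal(lab[["onlyLow"]], "negative")    # 1 uM record alone = tested
  expect_equal(lab[["never"]], "untested")
  expect_equal(cls[["never"]], "untested")
  expect_true(ann$lqt_flag[ann$drug_id == "both"])

  expect_error(label_inhibitors(tab[c(1, 1), ]), "duplicate drug_id")
  wild <- tibble::tibble(drug_id = "w", pct_inhib_1uM = NA,
                         pct_inhib_10uM = 400)
  expect_warning(label_inhibitors(wild), "outside")
  # custom threshold
  ann2 <- label_inhibitors(tab, threshold = 95)
  expect_equal(ann2$label[ann2$drug_id == "both"], "negative")
})

test_that("hypergeometric_test matches exact enumeration on a small urn", {
  # N=10, K=4 successes, draw n=5, observe k=3
  expect_equal(hypergeometric_test(10, 4, 5, 3, "upper"), 66 / 252)
  expect_equal(hypergeometric_test(10, 4, 5, 3, "upper", strict = TRUE),
               6 / 252)
  expect_equal(hypergeometric_test(10, 4, 5, 1, "lower"), 66 / 252)
  expect_equal(hypergeometric_test(10, 4, 5, 1, "lower", strict = TRUE),
               6 / 252)
  expect_equal(hypergeometric_test(10, 4, 5, 0, "lower", strict = TRUE), 0)
  expect_equal(hypergeometric_test(10, 4, 5, 0, "upper"), 1)
  # remains finite and positive deep in the tail
  expect_gt(hypergeometric_test(10000, 100, 500, 90, "upper"), 0)
  expect_error(hypergeometric_test(10, 12, 5, 3), "inconsistent")
  expect_error(hypergeometric_test(10, 4, 5, 5), "inconsistent")
})

test_that("permutation enrichment agrees with the hypergeometric law", {
  # 100 annotated drugs, 50 inhibitors; cluster A holds 10 with 8 inhibitors
  drugs <- sprintf("d%03d", 1:100)
  assign <- setNames(c(rep("A", 10), rep("B", 90)), drugs)
  labels <- setNames(rep("negative", 100), drugs)
  labels[c(1:8, 11:52)] <- "inhibitor"
  res <- cluster_enrichment_permutation(assign, labels, n_perm = 10000,
                                        seed = 42)
  a <- res[res$cluster_id == "A", ]
  expect_equal(a$n_members, 10L)
  expect_equal(a$n_annotated, 10L)
  expect_equal(a$n_inhibitors, 8L)
  expect_equal(a$fraction, 0.8)
  p_true <- phyper(7, 50, 50, 10, lower.tail = FALSE)
  mc_se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(a$empirical_p - p_true), 3 * mc_se + 1e-12)
  expect_equal(a$hypergeom_p, p_true)
})

test_that("zero permutation exceedances report below-resolution p-values", {
  drugs <- sprintf("d%03d", 1:60)
  assign <- setNames(c(rep("A", 12), rep("B", 48)), drugs)
  labels <- setNames(rep("negative", 60), drugs)
  labels[1:12] <- "inhibitor"   # all 12 inhibitors sit in cluster A
  res <- cluster_enrichment_permutation(assign, labels, n_perm = 1000,
                                        seed = 1)
  a <- res[res$cluster_id == "A", ]
  expect_equal(a$empirical_p, 0)
  expect_true(a$below_resolution)
  expect_equal(a$p_display, "<0.001")
  expect_true(a$bh_significant)
  res2 <- cluster_enrichment_permutation(assign, labels, n_perm = 1000,
                                         seed = 1, estimator = "add_one")
  a2 <- res2[res2$cluster_id == "A", ]
  expect_equal(a2$empirical_p, 1 / 1001)
  expect_false(a2$below_resolution)
})

test_that("untested drugs are excluded from enrichment counts", {
  assign <- setNames(rep(c("A", "B"), each = 5), sprintf("d%d", 1:10))
  labels <- setNames(c("inhibitor", "inhibitor", "untested", "untested",
                       "negative", rep("negative", 5)), sprintf("d%d", 1:10))
  res <- cluster_enrichment_permutation(assign, labels, n_perm = 100, seed = 1)
  a <- res[res$cluster_id == "A", ]
  expect_equal(a$n_members, 5L)
  expect_equal(a$n_annotated, 3L)
  expect_equal(a$n_inhibitors, 2L)
  all_untested <- setNames(rep("untested", 10), sprintf("d%d", 1:10))
  expect_error(cluster_enrichment_permutation(assign, all_untested),
               "no annotated drug")
})

test_that("BH adjustment reproduces the step-up rule by hand", {
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.5), fdr = 0.2)
  expect_equal(out$adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  out2 <- bh_adjust(c(0.04, 0.9), fdr = 0.2)
  expect_equal(out2$adjusted, c(0.08, 0.9))
  expect_equal(out2$significant, c(TRUE, FALSE))
  expect_error(bh_adjust(c(0.1, 1.2)), "p_values")
})

test_that("prediction statistics match a hand-built confusion matrix", {
  ids <- sprintf("d%02d", 1:12)
  assign <- setNames(c(rep("E", 4), rep("O", 8)), ids)
  labels <- setNames(c("inhibitor", "inhibitor", "inhibitor", "negative",
                       "inhibitor", "inhibitor", rep("negative", 5),
                       "untested"), ids)
  st <- prediction_stats(assign, "E", labels)
  expect_equal(st$tp, 3)
  expect_equal(st$fp, 1)
  expect_equal(st$fn, 2)
  expect_equal(st$tn, 5)
  expect_equal(st$sensitivity, 3 / 5)
  expect_equal(st$specificity, 5 / 6)
  expect_equal(st$accuracy, 8 / 11)
  # no enriched clusters: everything is called negative
  st0 <- prediction_stats(assign, character(0), labels)
  expect_equal(st0$tp + st0$fp, 0)
  expect_equal(st0$sensitivity, 0)
  expect_equal(st0$specificity, 1)
})

test_that("rank-sum test reproduces the exact small-sample p-value", {
  rs <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 0.1)   # 2 * 1/C(6,3)
  rs2 <- rank_sum_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(rs2$p_value, 0.1)
  # ties fall back to the corrected normal approximation without error
  rs3 <- rank_sum_test(c(1, 1, 2, 2), c(1, 2, 3, 3))
  expect_true(rs3$p_value > 0 && rs3$p_value <= 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "length")
})

test_that("the enrichment table is tidy and plots without error", {
  res <- small_pipeline()
  enr <- res$enrichment
  expect_s3_class(enr, "herg_enrichment")
  expect_true(all(c("cluster_id", "fraction", "empirical_p", "bh_adjusted",
                    "bh_significant", "hypergeom_p") %in% names(enr)))
  expect_equal(sum(enr$n_members), length(res$hierarchy$levels[[1]]$ids))
  expect_true(all(enr$empirical_p >= 0 & enr$empirical_p <= 1))
  expect_true(all(enr$bh_adjusted >= enr$empirical_p - 1e-12 |
                    enr$below_resolution | enr$n_annotated == 0))
  p <- ggplot2::autoplot(enr)
  expect_s3_class(p, "ggplot")
})
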