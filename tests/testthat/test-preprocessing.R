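test_that("select_arrays keeps one platform and strictly large batches", {
  v <- matrix(rnorm(24), 4, 6)
  cmp <- mk_compendium(v, batch_id = c("b1", "b1", "b1", "b2", "b2", "b2"),
                       platform_id = c("P1", "P1", "P1", "P1", "P1", "P2"))
  out <- select_arrays(cmp, "P1", min_batch_size = 2)
  # b2 has only 2 arrays on P1: 2 > 2 is false, so only b1 survives
  expect_setequal(out$metadata$array_id, c("a01", "a02", "a03"))
  expect_true(all(out$metadata$platform_id == "P1"))
  # boundary: batch of exactly min_batch_size arrays is dropped
  expect_setequal(select_arrays(cmp, "P1", 1)$metadata$batch_id, c("b1", "b2"))
  expect_error(select_arrays(cmp, "P3"), "no arrays on platform")
  expect_error(select_arrays(cmp, "P1", 10), "no batch exceeds")
})

test_that("select_mode_concentration keeps the modal dose, ties to the lowest", {
  v <- matrix(rnorm(18), 3, 6)
  cmp <- mk_compendium(v, batch_id = "b1",
                       drug_id = c("d1", "d1", "d1", "d2", "d2", "VEHICLE"),
                       concentration = c(1, 1, 10, 1, 10, 0),
                       vehicle = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- select_mode_concentration(cmp)
  m <- out$metadata
  # d1: mode is 1 uM (2 of 3 arrays); d2: 1-vs-10 tie resolves to 1 uM
  expect_setequal(m$array_id[m$drug_id == "d1"], c("a01", "a02"))
  expect_setequal(m$array_id[m$drug_id == "d2"], "a04")
  expect_true("a06" %in% m$array_id)  # vehicle untouched
})

test_that("batch_center removes the per-batch probeset mean exactly", {
  set.seed(11)
  v <- matrix(rnorm(24, mean = 7), 4, 6)
  batch <- c("b1", "b1", "b1", "b2", "b2", "b2")
  veh <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  cmp <- mk_compendium(v, batch_id = batch, vehicle = veh)
  cen <- batch_center(cmp)
  all_centered <- cbind(cen$profiles$values, cen$controls$values)
  all_centered <- all_centered[, cmp$metadata$array_id]
  for (b in unique(batch)) {
    expect_equal(rowMeans(all_centered[, batch == b]), rep(0, 4),
                 ignore_attr = TRUE)
  }
  # centered value is original minus batch mean (vehicle included in mean)
  expect_equal(cen$profiles$values[, "a01"],
               v[, 1] - rowMeans(v[, 1:3]), ignore_attr = TRUE)
  expect_true(all(cen$controls$info$drug_id == "VEHICLE"))
  small <- mk_compendium(matrix(rnorm(8), 4, 2), batch_id = c("b1", "b2"))
  expect_error(batch_center(small), "single array")
})

test_that("silent filter applies the exact count and up-regulation thresholds", {
  v <- matrix(0, 20, 4)
  v[1:9, 1] <- 2    # keepA: 10 probesets at |v| >= 2 ...
  v[10, 1]  <- 3    # ... one of which is >= +3
  v[1:8, 2] <- 2    # failN: only 9 probesets reach |v| >= 2
  v[9, 2]   <- 3
  v[1:12, 3] <- -2.5  # failUp: 12 probesets pass |v| >= 2, none up >= 3
  v[1:5, 4] <- 2      # failBoth: too few probesets and none up >= 3
  colnames(v) <- c("keepA", "failN", "failUp", "failBoth")
  p <- mk_profiles(v)
  out <- filter_silent(p)
  expect_identical(colnames(out$kept$values), "keepA")
  expect_setequal(out$removed_ids$profile_id,
                  c("failN", "failUp", "failBoth"))
  # disjunctive rule keeps profiles satisfying either condition alone
  out_either <- filter_silent(p, rule = "either")
  expect_setequal(colnames(out_either$kept$values),
                  c("keepA", "failN", "failUp"))
  expect_error(filter_silent(mk_profiles(matrix(0, 20, 2))),
               "removed every profile")
})

test_that("de_mask zeroes values inside the control percentile band, inclusive", {
  ctrl_v <- rbind(c(-1, -0.5, 0, 0.5, 1),
                  c(-10, -5, 0, 5, 10))
  colnames(ctrl_v) <- sprintf("c%02d", 1:5)
  rownames(ctrl_v) <- c("g01", "g02")
  controls <- mk_profiles(ctrl_v, cell_line = "A")
  # type-7 quantiles of 5 points at 2.5% / 97.5%: row 1 -> [-0.95, 0.95]
  dv <- cbind(p01 = c(0.4, 9.5), p02 = c(2, -9.6))
  rownames(dv) <- c("g01", "g02")
  profiles <- mk_profiles(dv, cell_line = "A")
  masked <- de_mask(profiles, controls)
  expect_true(masked$masked)
  expect_equal(unname(masked$values[, "p01"]), c(0, 0))   # 9.5 is boundary
  expect_equal(unname(masked$values[, "p02"]), c(2, -9.6))
  # per-cell-line bands: wide controls in cell line B mask everything
  ctrl_b <- matrix(seq(-100, 100, length.out = 10), 2, 10, byrow = TRUE)
  colnames(ctrl_b) <- sprintf("cb%02d", 1:10)
  rownames(ctrl_b) <- c("g01", "g02")
  both_ctrl <- mk_profiles(cbind(ctrl_v, ctrl_b),
                           cell_line = rep(c("A", "B"), c(5, 10)))
  both_prof <- mk_profiles(cbind(dv, pB = c(2, -9.6)),
                           cell_line = c("A", "A", "B"))
  masked2 <- de_mask(both_prof, both_ctrl)
  expect_equal(unname(masked2$values[, "pB"]), c(0, 0))
  expect_equal(masked2$values[, "p02"], masked$values[, "p02"])
  lone <- mk_profiles(matrix(rnorm(2), 2, 1,
                             dimnames = list(c("g01", "g02"), "cx")),
                      cell_line = "C")
  expect_error(de_mask(mk_profiles(dv, cell_line = "C"), lone),
               "at least 2 vehicle control arrays")
})

test_that("merge_replicates averages per (drug, cell line) pair", {
  v <- matrix(c(1, 2, 3, 4, 10, 20), 2, 3)
  colnames(v) <- c("p01", "p02", "p03")
  rownames(v) <- c("g01", "g02")
  p <- mk_profiles(v, drug_id = c("d1", "d1", "d2"), cell_line = "A")
  m <- merge_replicates(p)
  expect_setequal(m$info$profile_id, c("d1@A", "d2@A"))
  expect_equal(unname(m$values[, "d1@A"]), c(2, 3))
  expect_equal(unname(m$values[, "d2@A"]), c(10, 20))
  expect_equal(m$info$n_replicates_merged[match(c("d1@A", "d2@A"),
                                                m$info$profile_id)], c(2L, 1L))
  # same drug in two cell lines stays separate
  p2 <- mk_profiles(v, drug_id = "d1", cell_line = c("A", "A", "B"))
  expect_setequal(merge_replicates(p2)$info$profile_id, c("d1@A", "d1@B"))
})

test_that("processing_report counts arrays and disjoint annotation classes", {
  v <- matrix(rnorm(20), 4, 5)
  cmp <- mk_compendium(v, batch_id = "b1",
                       drug_id = c("d1", "d1", "d2", "d3", "VEHICLE"),
                       vehicle = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ann <- tibble::tibble(drug_id = c("d1", "d2", "d3"),
                        class = c("experimental", "lqt", "negative"))
  rep1 <- processing_report(list(input = cmp), ann)
  expect_equal(rep1$n_arrays, 4)            # vehicle excluded
  expect_equal(rep1$n_unique_drugs, 3)
  expect_equal(rep1$n_experimental, 2)      # d1 has two arrays
  expect_equal(rep1$n_experimental_unique, 1)
  expect_equal(rep1$n_lqt, 1)
  expect_equal(rep1$n_lqt_unique, 1)
  # profiles snapshots are accepted too, and stages keep their order
  prof <- mk_profiles(matrix(rnorm(8), 4, 2), drug_id = c("d1", "d2"))
  rep2 <- processing_report(list(input = cmp, merged = prof), ann)
  expect_equal(rep2$stage, c("input", "merged"))
  expect_equal(rep2$n_arrays[2], 2)
})

test_that("the pipeline report matches a hand count on the full run", {
  res <- small_pipeline()
  rep <- res$report
  expect_equal(rep$stage, c("input", "batch_selected", "non_silent", "merged"))
  # counts never increase along the pipeline
  expect_true(all(diff(rep$n_arrays) <= 0))
  expect_true(all(diff(rep$n_unique_drugs) <= 0))
  # merged stage has one profile per kept (drug, cell line) pair
  expect_equal(rep$n_arrays[4], ncol(res$profiles$values))
  expect_equal(rep$n_unique_drugs[4], length(unique(res$profiles$info$drug_id)))
})
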