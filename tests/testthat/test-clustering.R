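test_that("pearson_similarity reproduces a hand-computed correlation", {
  v <- cbind(x = c(1, 2, 3), y = c(1, 2, 4))
  rownames(v) <- c("g1", "g2", "g3")
  sim <- pearson_similarity(v)
  expect_equal(sim$S["x", "y"], 0.981980506, tolerance = 1e-8)
  expect_equal(sim$S["y", "x"], sim$S["x", "y"])
  # sole off-diagonal value doubles as the median preference
  expect_equal(sim$preference, sim$S["x", "y"])
  expect_equal(unname(diag(sim$S)), rep(sim$preference, 2))
  flat <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(pearson_similarity(flat), "zero-variance")
})

test_that("set_preference uses the median off-diagonal similarity", {
  S <- diag(4)
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  S[upper.tri(S)] <- vals
  S <- S + t(S) - diag(diag(S))
  dimnames(S) <- list(letters[1:4], letters[1:4])
  sim <- set_preference(S)
  expect_equal(sim$preference, median(vals))
  sim2 <- set_preference(S, preference = -1.5)
  expect_equal(unname(diag(sim2$S)), rep(-1.5, 4))
  expect_equal(sim2$preference, -1.5)
})

test_that("affinity propagation is near-optimal against exhaustive search", {
  for (s in 1:10) {
    S <- with_seed(s, {
      v <- matrix(rnorm(8 * 30), 30, 8,
                  dimnames = list(NULL, sprintf("i%d", 1:8)))
      cor(v)
    })
    sim <- set_preference(S)
    cl <- affinity_propagation(sim, damping = 0.5, seed = s)
    best <- brute_force_best(sim)
    expect_gte(cl$net_similarity, best - abs(best) * 0.05)
    expect_equal(net_similarity(sim, cl$exemplars), cl$net_similarity,
                 tolerance = 1e-9)
  }
})

test_that("affinity propagation recovers two well-separated blocks", {
  n <- 10
  S <- matrix(-0.5, n, n)
  S[1:5, 1:5] <- 0.9
  S[6:10, 6:10] <- 0.9
  jit <- with_seed(3, matrix(rnorm(n * n, 0, 0.01), n, n))
  S <- S + (jit + t(jit)) / 2
  dimnames(S) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
  cl <- affinity_propagation(set_preference(S), seed = 1)
  expect_true(cl$converged)
  expect_length(cl$exemplars, 2)
  expect_length(unique(cl$assignment[1:5]), 1)
  expect_length(unique(cl$assignment[6:10]), 1)
  expect_false(cl$assignment[1] == cl$assignment[6])
  # exemplars are assigned to themselves and weights match the matrix
  expect_true(all(cl$assignment[cl$exemplars] == cl$exemplars))
  i <- setdiff(cl$ids, cl$exemplars)[1]
  expect_equal(unname(cl$weight[i]), S[i, cl$assignment[i]], tolerance = 1e-6)
})

test_that("a flat similarity with low preference collapses to one cluster", {
  n <- 6
  S <- matrix(0.8, n, n)
  dimnames(S) <- list(letters[1:n], letters[1:n])
  cl <- affinity_propagation(set_preference(S, preference = -2), seed = 4)
  expect_length(cl$exemplars, 1)
  expect_length(unique(cl$assignment), 1)
})

test_that("clustering is deterministic for a fixed seed", {
  v <- with_seed(9, matrix(rnorm(40 * 12), 40, 12,
                           dimnames = list(sprintf("g%02d", 1:40),
                                           sprintf("i%02d", 1:12))))
  sim <- pearson_similarity(v)
  a <- affinity_propagation(sim, seed = 2)
  b <- affinity_propagation(sim, seed = 2)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$net_similarity, b$net_similarity)
  h1 <- recursive_cluster(v, seed = 2)
  h2 <- recursive_cluster(v, seed = 2)
  expect_identical(lapply(h1$levels, `[[`, "assignment"),
                   lapply(h2$levels, `[[`, "assignment"))
})

test_that("recursive clustering builds a two-tier hierarchy on nested structure", {
  # 2 families x 2 subclusters x 5 members: shared family base plus a
  # smaller subcluster effect, so level 0 finds 4 subclusters and level 1
  # merges them into the 2 families
  p <- 200
  mk <- with_seed(17, {
    fam <- replicate(2, rnorm(p))
    sub <- replicate(4, rnorm(p))
    cols <- lapply(1:20, function(i) {
      s <- (i - 1) %/% 5 + 1          # subcluster 1..4
      f <- (s - 1) %/% 2 + 1          # family 1..2
      fam[, f] + 0.8 * sub[, s] + 0.15 * rnorm(p)
    })
    m <- do.call(cbind, cols)
    dimnames(m) <- list(sprintf("g%03d", 1:p), sprintf("m%02d", 1:20))
    m
  })
  h <- recursive_cluster(mk, seed = 1)
  k <- vapply(h$levels, function(l) length(l$exemplars), integer(1))
  expect_gte(length(k), 2)
  expect_true(all(diff(k) < 0))
  sub_truth <- rep(1:4, each = 5)
  expect_equal(adjusted_rand_index(h$levels[[1]]$assignment,
                                   setNames(sub_truth, sprintf("m%02d", 1:20))), 1)
  # the top level separates the two families
  top <- h$levels[[length(h$levels)]]
  l0 <- h$levels[[1]]$assignment
  chain <- l0
  for (lvl in h$levels[-1]) chain <- lvl$assignment[chain]
  fam_truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand_index(chain, setNames(fam_truth, names(chain))), 1)
  # preference is inherited from level 0 at every level
  expect_true(all(vapply(h$levels, `[[`, numeric(1), "preference") ==
                    h$preference))
})

test_that("network export and file writing round-trip the hierarchy", {
  res <- small_pipeline()
  net <- res$network
  l0 <- res$hierarchy$levels[[1]]
  expect_setequal(net$nodes$profile_id, l0$ids)
  expect_setequal(unique(net$nodes$cluster), l0$exemplars)
  expect_equal(sum(net$nodes$is_exemplar), length(l0$exemplars))
  # one edge per non-exemplar member at level 0
  e0 <- net$edges[net$edges$level == 0, ]
  expect_equal(nrow(e0), length(l0$ids) - length(l0$exemplars))
  expect_true(all(e0$exemplar %in% l0$exemplars))
  expect_true(all(net$nodes$class %in%
                    c("experimental", "lqt", "negative", "untested")))
  expect_setequal(net$nodes$cluster[net$nodes$enriched], res$enriched_ids)

  dir <- file.path(tempdir(), "hergnet-network-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  sif <- readLines(file.path(dir, "network.sif"))
  expect_length(sif, nrow(net$edges))
  expect_match(sif[1], "^\\S+ pp \\S+$")
  members <- jsonlite::read_json(file.path(dir, "clusters.json"),
                                 simplifyVector = TRUE)
  expect_setequal(names(members), l0$exemplars)
  expect_setequal(unlist(members), l0$ids)
})
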