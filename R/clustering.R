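#' Pairwise Pearson similarity of response profiles
#'
#' Computes the full Pearson correlation matrix over profiles and places
#' the affinity-propagation preference (the median off-diagonal pairwise
#' correlation, see [set_preference()]) on the diagonal.
#'
#' @param profiles A [new_profiles()] object or a numeric matrix with
#'   items in columns.
#' @return A `herg_similarity` object: list with `ids`, the symmetric
#'   matrix `S`, and the scalar `preference`.
#' @export
pearson_similarity <- function(profiles) {
  v <- if (inherits(profiles, "herg_profiles")) profiles$values else profiles
  stopifnot(is.matrix(v), ncol(v) >= 2)
  vars <- apply(v, 2, stats::var)
  if (any(vars == 0)) {
    abort(paste0("zero-variance profile(s): ",
                 paste(colnames(v)[vars == 0], collapse = ", ")))
  }
  S <- cor(v)
  sim <- structure(list(ids = colnames(v), S = S, preference = NA_real_),
                   class = "herg_similarity")
  set_preference(sim)
}

#' Set the affinity-propagation preference to the median pairwise similarity
#'
#' The shared diagonal preference controls how readily items become cluster
#' exemplars; following the median-of-pairwise-correlations rule, it is the
#' median of the off-diagonal upper-triangle similarities. The value is
#' stored so that hierarchy levels can reuse the level-0 preference.
#'
#' @param sim A `herg_similarity` object (or bare similarity matrix).
#' @param preference Optional explicit preference overriding the median.
#' @return The `herg_similarity` with every diagonal entry set.
#' @export
set_preference <- function(sim, preference = NULL) {
  if (is.matrix(sim)) {
    sim <- structure(list(ids = colnames(sim), S = sim,
                          preference = NA_real_), class = "herg_similarity")
  }
  stopifnot(nrow(sim$S) >= 2)
  p <- preference %||% median(sim$S[upper.tri(sim$S)])
  diag(sim$S) <- p
  sim$preference <- p
  sim
}

#' Affinity propagation clustering
#'
#' Message-passing exemplar clustering. Responsibilities and availabilities
#' are iterated with damping until the exemplar set is stable for
#' `conv_iter` consecutive iterations:
#' \deqn{r(i,k) \leftarrow s(i,k) - \max_{k' \neq k}[a(i,k') + s(i,k')]}
#' \deqn{a(i,k) \leftarrow \min(0,\; r(k,k) + \sum_{i' \notin \{i,k\}} \max(0, r(i',k))), \quad i \neq k}
#' \deqn{a(k,k) \leftarrow \sum_{i' \neq k} \max(0, r(i',k))}
#' Exemplars are the items with \eqn{r(k,k)+a(k,k) > 0}; every other item
#' is assigned to its most similar exemplar. A seeded symmetric jitter of
#' magnitude 1e-12 breaks exact degeneracies.
#'
#' @param sim A `herg_similarity` from [pearson_similarity()] /
#'   [set_preference()].
#' @param damping Message damping factor in [0.5, 1) (default 0.9).
#' @param max_iter Maximum iterations (default 1000).
#' @param conv_iter Stability window for convergence (default 50).
#' @param seed Seed for the degeneracy-breaking jitter.
#' @return An `ap_clustering` object: list with `ids`, `exemplars`,
#'   `assignment` (named vector item -> exemplar id), `weight` (named
#'   similarity of each item to its exemplar), `n_iterations`, `converged`,
#'   `net_similarity`, `preference`.
#' @export
affinity_propagation <- function(sim, damping = 0.9, max_iter = 1000,
                                 conv_iter = 50, seed = 1L) {
  stopifnot(inherits(sim, "herg_similarity"),
            damping >= 0.5, damping < 1)
  S0 <- sim$S
  n <- nrow(S0)
  ids <- sim$ids
  S <- with_seed(derive_seed(seed, "ap-jitter"), {
    e <- matrix(runif(n * n, -1, 1), n, n) * 1e-12
    S0 + (e + t(e)) / 2
  })
  R <- A <- matrix(0, n, n)
  idx <- seq_len(n)
  prev_ex <- integer(0)
  stable <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    AS <- A + S
    j1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, j1)]
    AS[cbind(idx, j1)] <- -Inf
    j2 <- max.col(AS, ties.method = "first")
    m2 <- AS[cbind(idx, j2)]
    Rnew <- S - m1
    Rnew[cbind(idx, j1)] <- S[cbind(idx, j1)] - m2
    R <- damping * R + (1 - damping) * Rnew

    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) > 0 && identical(ex, prev_ex)) {
      stable <- stable + 1L
      if (stable >= conv_iter) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    prev_ex <- ex
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0) {
    warn("affinity propagation: no exemplar emerged; returning best iterate")
    ex <- which.max(diag(R) + diag(A))
    converged <- FALSE
  }
  if (!converged && length(ex) > 0 && stable < conv_iter && iter >= max_iter) {
    warn("affinity propagation did not converge within max_iter")
  }
  assign_idx <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_idx[ex] <- ex
  assignment <- setNames(ids[assign_idx], ids)
  weight <- setNames(S0[cbind(idx, assign_idx)], ids)
  net <- sum(S0[cbind(setdiff(idx, ex), assign_idx[setdiff(idx, ex)])]) +
    length(ex) * sim$preference
  structure(list(ids = ids, exemplars = ids[ex], assignment = assignment,
                 weight = weight, n_iterations = iter, converged = converged,
                 net_similarity = net, preference = sim$preference),
            class = "ap_clustering")
}

#' @export
print.ap_clustering <- function(x, ...) {
  cat("<ap_clustering> ", length(x$ids), " items, ",
      length(x$exemplars), " clusters",
      if (!x$converged) " (NOT converged)",
      "; net similarity ", signif(x$net_similarity, 4), "\n", sep = "")
  invisible(x)
}

#' Recursively cluster exemplars into a hierarchy
#'
#' Level 0 clusters all profiles by affinity propagation; each subsequent
#' level clusters the previous level's exemplars using the similarity
#' sub-matrix restricted to them, with the diagonal preference held at the
#' level-0 value. Recursion stops when the exemplar count no longer
#' decreases or a single exemplar remains, i.e. when the clusters cannot
#' be merged further.
#'
#' @param profiles A [new_profiles()] object (or numeric matrix).
#' @inheritParams affinity_propagation
#' @return A `herg_hierarchy`: list with `levels` (list of `ap_clustering`),
#'   `terminal` flag, `preference`, `similarity` (the level-0
#'   `herg_similarity`) and `info` (profile metadata if available).
#' @export
recursive_cluster <- function(profiles, damping = 0.9, max_iter = 1000,
                              conv_iter = 50, seed = 1L) {
  sim <- pearson_similarity(profiles)
  info <- if (inherits(profiles, "herg_profiles")) profiles$info else NULL
  levels <- list(affinity_propagation(sim, damping, max_iter, conv_iter, seed))
  repeat {
    items <- levels[[length(levels)]]$exemplars
    if (length(items) < 2) break
    sub <- sim$S[items, items, drop = FALSE]
    sub_sim <- set_preference(
      structure(list(ids = items, S = sub, preference = NA_real_),
                class = "herg_similarity"),
      preference = sim$preference)
    nxt <- affinity_propagation(sub_sim, damping, max_iter, conv_iter,
                                seed = seed + length(levels))
    if (length(nxt$exemplars) >= length(items)) break
    levels <- c(levels, list(nxt))
  }
  structure(list(levels = levels, terminal = TRUE,
                 preference = sim$preference, similarity = sim, info = info),
            class = "herg_hierarchy")
}

#' @export
print.herg_hierarchy <- function(x, ...) {
  cat("<herg_hierarchy> ", length(x$levels), " level(s): ",
      paste(vapply(x$levels, function(l) length(l$exemplars), integer(1)),
            collapse = " -> "), " exemplars\n", sep = "")
  invisible(x)
}

#' Export a cluster hierarchy as network node and edge tables
#'
#' Produces Cytoscape-style tables: one edge per member-to-exemplar link at
#' every hierarchy level (weighted by the Pearson similarity to the
#' exemplar), and one node row per level-0 profile with its cluster,
#' exemplar status, hERG annotation class and enriched-cluster flag.
#'
#' @param h A `herg_hierarchy` from [recursive_cluster()].
#' @param annotations Optional annotation tibble from [label_inhibitors()];
#'   profiles without a record are classed `"untested"`.
#' @param enriched_ids Character vector of enriched level-0 cluster
#'   (exemplar) ids.
#' @return A list with tibbles `edges` (level, member, exemplar, weight)
#'   and `nodes` (profile_id, drug_id, cell_line, cluster, is_exemplar,
#'   class, enriched).
#' @export
export_network <- function(h, annotations = NULL, enriched_ids = character()) {
  edges <- purrr::imap_dfr(h$levels, function(cl, lvl) {
    keep <- cl$assignment != names(cl$assignment)
    tibble(level = lvl - 1L,
           member = names(cl$assignment)[keep],
           exemplar = unname(cl$assignment[keep]),
           weight = unname(cl$weight[keep]))
  })
  l0 <- h$levels[[1]]
  nodes <- tibble(profile_id = l0$ids,
                  cluster = unname(l0$assignment),
                  is_exemplar = l0$ids %in% l0$exemplars)
  if (!is.null(h$info)) {
    nodes <- dplyr::left_join(nodes,
                              h$info[, c("profile_id", "drug_id", "cell_line")],
                              by = "profile_id")
  } else {
    nodes$drug_id <- nodes$profile_id
    nodes$cell_line <- NA_character_
  }
  if (!is.null(annotations)) {
    nodes <- dplyr::left_join(nodes,
                              annotations[, c("drug_id", "class")],
                              by = "drug_id")
    nodes$class[is.na(nodes$class)] <- "untested"
  } else {
    nodes$class <- "untested"
  }
  nodes$enriched <- nodes$cluster %in% enriched_ids
  nodes <- nodes[, c("profile_id", "drug_id", "cell_line", "cluster",
                     "is_exemplar", "class", "enriched")]
  list(edges = edges, nodes = nodes)
}

#' Write network files for external visualization
#'
#' Writes a SIF edge list (`member pp exemplar`), TSV edge- and
#' node-attribute tables, and a JSON file of level-0 cluster membership
#' keyed by exemplar id.
#'
#' @param network List from [export_network()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(dir, "network.sif")
  writeLines(sprintf("%s pp %s", network$edges$member, network$edges$exemplar),
             sif)
  ea <- file.path(dir, "edge_attributes.tsv")
  readr::write_tsv(network$edges, ea)
  na <- file.path(dir, "node_attributes.tsv")
  readr::write_tsv(network$nodes, na)
  members <- split(network$nodes$profile_id, network$nodes$cluster)
  mj <- file.path(dir, "clusters.json")
  jsonlite::write_json(members, mj, pretty = TRUE)
  invisible(c(sif, ea, na, mj))
}

#' Net similarity of an exemplar-set clustering
#'
#' Objective maximized by affinity propagation: the sum of each
#' non-exemplar's similarity to its exemplar plus the preference for each
#' exemplar. Used for comparing clusterings of one similarity matrix.
#'
#' @param sim A `herg_similarity`.
#' @param exemplars Character vector of exemplar ids.
#' @return Scalar net similarity; items are assigned to their most similar
#'   exemplar.
#' @export
net_similarity <- function(sim, exemplars) {
  stopifnot(all(exemplars %in% sim$ids))
  ex <- match(exemplars, sim$ids)
  S <- sim$S
  non <- setdiff(seq_along(sim$ids), ex)
  s <- if (length(non) > 0) {
    sum(apply(S[non, ex, drop = FALSE], 1, max))
  } else 0
  s + length(ex) * sim$preference
}
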