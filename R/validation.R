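#' Correlation between hERG activity and similarity to enriched exemplars
#'
#' For every drug with a measured percent-inhibition value, computes the
#' maximum Pearson correlation of its response profile to any enriched
#' cluster exemplar profile, then the Pearson correlation `r` between
#' activity and that maximum similarity. Significance is assessed by
#' permuting the activity values `n_perm` times (two-sided on `|r|`). The
#' fraction of drugs inside enriched clusters is also reported per window
#' of activity values.
#'
#' @param activities Named numeric vector: drug (profile) id -> percent
#'   hERG inhibition.
#' @param profiles A [new_profiles()] object containing the measured drugs
#'   and the exemplars.
#' @param enriched_exemplar_ids Profile ids of the enriched-cluster
#'   exemplars.
#' @param clustering Optional `ap_clustering` used for the windowed
#'   enriched fraction; defaults to counting drugs whose best exemplar
#'   correlation is to an enriched exemplar only if omitted.
#' @param n_perm Number of activity permutations (default 1000).
#' @param window Width of the activity windows, percentage points
#'   (default 10).
#' @param seed Integer seed.
#' @return A list with `r`, `permutation_p`, `per_drug` (tibble: id,
#'   activity, max_cor, in_enriched) and `windowed` (tibble: window_lo,
#'   window_hi, n, fraction_enriched).
#' @export
activity_similarity_analysis <- function(activities, profiles,
                                         enriched_exemplar_ids,
                                         clustering = NULL,
                                         n_perm = 1000, window = 10,
                                         seed = 1L) {
  if (length(enriched_exemplar_ids) == 0) {
    abort("no enriched exemplars supplied")
  }
  ids <- intersect(names(activities), colnames(profiles$values))
  if (length(ids) < 3) abort("need at least 3 drugs with activity measurements")
  missing_ex <- setdiff(enriched_exemplar_ids, colnames(profiles$values))
  if (length(missing_ex) > 0) {
    abort(paste0("exemplar profiles missing: ", paste(missing_ex, collapse = ", ")))
  }
  act <- activities[ids]
  cors <- cor(profiles$values[, ids, drop = FALSE],
              profiles$values[, enriched_exemplar_ids, drop = FALSE])
  max_cor <- apply(cors, 1, max)
  r <- cor(act, max_cor)
  perm_ge <- with_seed(derive_seed(seed, "activity-perm"), {
    sum(vapply(seq_len(n_perm), function(p) {
      abs(cor(sample(act), max_cor)) >= abs(r)
    }, logical(1)))
  })
  permutation_p <- perm_ge / n_perm

  in_enr <- if (!is.null(clustering)) {
    unname(clustering$assignment[ids] %in% enriched_exemplar_ids)
  } else {
    apply(cors, 1, which.max) |>
      (\(j) colnames(cors)[j] %in% enriched_exemplar_ids)()
  }
  breaks <- seq(floor(min(act) / window) * window,
                ceiling(max(act) / window) * window + window, by = window)
  bin <- cut(act, breaks = breaks, right = FALSE, include.lowest = TRUE)
  windowed <- tibble(window_lo = breaks[as.integer(bin)],
                     window_hi = breaks[as.integer(bin) + 1],
                     in_enriched = in_enr) |>
    dplyr::group_by(.data$window_lo, .data$window_hi) |>
    dplyr::summarise(n = dplyr::n(),
                     fraction_enriched = mean(.data$in_enriched),
                     .groups = "drop")
  list(r = r,
       permutation_p = permutation_p,
       p_display = if (perm_ge == 0) sprintf("<%g", 1 / n_perm)
       else sprintf("%g", permutation_p),
       per_drug = tibble(id = ids, activity = unname(act),
                         max_cor = unname(max_cor), in_enriched = in_enr),
       windowed = windowed)
}

#' Random-set validation of mean hERG inhibition
#'
#' Compares the mean percent inhibition of an observed compound set to the
#' means of `n_sets` random sets of the same size drawn (without
#' replacement within a set) from the pool of experimental measurements.
#' The empirical p-value is the fraction of random-set means at or above
#' the observed mean, reported as `"<1/n_sets"` when no random set
#' reaches it.
#'
#' @param activity_pool Numeric vector of percent-inhibition measurements.
#' @param observed_values Percent inhibition of the validated compounds;
#'   its length sets the random-set size.
#' @param n_sets Number of random sets (default 1000).
#' @param seed Integer seed.
#' @return A list with `observed_mean`, `null_means`, `empirical_p`,
#'   `p_display`, `set_size`.
#' @export
random_set_validation <- function(activity_pool, observed_values,
                                  n_sets = 1000, seed = 1L) {
  k <- length(observed_values)
  if (length(activity_pool) < k) {
    abort("activity pool smaller than the validated set")
  }
  observed_mean <- mean(observed_values)
  null_means <- with_seed(derive_seed(seed, "random-sets"), {
    vapply(seq_len(n_sets), function(i) mean(sample(activity_pool, k)),
           numeric(1))
  })
  ge <- sum(null_means >= observed_mean)
  list(observed_mean = observed_mean,
       null_means = null_means,
       empirical_p = ge / n_sets,
       p_display = if (ge == 0) sprintf("<%g", 1 / n_sets)
       else sprintf("%g", ge / n_sets),
       set_size = k)
}

#' Per-cluster response-signature summaries
#'
#' For each cluster, computes the probeset-wise mean and median response
#' across member profiles and derives the cluster signature gene sets: the
#' probesets up-regulated (median > 0) or down-regulated (median < 0) in
#' at least half of the members. Pairwise overlap counts of the up and
#' down sets between clusters are also returned.
#'
#' @param clustering An `ap_clustering` or named item -> cluster vector.
#' @param profiles [new_profiles()] containing every clustered item.
#' @return A list with `signatures` (list per cluster: `mean`, `median`,
#'   `up`, `down`) and `overlaps` (tibble: cluster_a, cluster_b,
#'   up_overlap, down_overlap).
#' @export
cluster_signature_summary <- function(clustering, profiles) {
  assignment <- if (inherits(clustering, "ap_clustering")) {
    clustering$assignment
  } else clustering
  stopifnot(length(assignment) > 0)
  members <- split(names(assignment), unname(assignment))
  signatures <- lapply(members, function(ids) {
    v <- profiles$values[, ids, drop = FALSE]
    med <- apply(v, 1, median)
    list(mean = rowMeans(v), median = med,
         up = rownames(profiles$values)[med > 0],
         down = rownames(profiles$values)[med < 0])
  })
  cl <- names(signatures)
  overlaps <- if (length(cl) >= 2) {
    pairs <- t(utils::combn(cl, 2))
    tibble(cluster_a = pairs[, 1], cluster_b = pairs[, 2],
           up_overlap = vapply(seq_len(nrow(pairs)), function(i)
             length(intersect(signatures[[pairs[i, 1]]]$up,
                              signatures[[pairs[i, 2]]]$up)), integer(1)),
           down_overlap = vapply(seq_len(nrow(pairs)), function(i)
             length(intersect(signatures[[pairs[i, 1]]]$down,
                              signatures[[pairs[i, 2]]]$down)), integer(1)))
  } else {
    tibble(cluster_a = character(), cluster_b = character(),
           up_overlap = integer(), down_overlap = integer())
  }
  list(signatures = signatures, overlaps = overlaps)
}
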