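#' Read a fingerprint table
#'
#' Parses a two-column TSV of circular-fingerprint feature sets:
#' `drug_id<TAB>comma-separated integer feature ids`.
#'
#' @param path Path to the fingerprint TSV (no header).
#' @return Named list of sorted integer feature-id vectors, one per drug.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) abort(paste0("fingerprint file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    tab <- regexpr("\t", lines[[i]], fixed = TRUE)
    id <- if (tab > 0) substr(lines[[i]], 1, tab - 1) else ""
    rest <- if (tab > 0) substring(lines[[i]], tab + 1) else ""
    if (tab < 0 || !nzchar(id) || grepl("\t", rest, fixed = TRUE)) {
      abort(sprintf("malformed fingerprint line %d: %s", i, lines[[i]]))
    }
    parts <- c(id, rest)
    feats <- suppressWarnings(as.integer(strsplit(rest, ",")[[1]]))
    if (length(feats) == 0 || all(is.na(feats) & !nzchar(trimws(rest)))) {
      warn(sprintf("fingerprint line %d (%s): empty feature list, record dropped",
                   i, parts[1]))
      next
    }
    if (anyNA(feats)) {
      abort(sprintf("malformed fingerprint line %d: non-integer feature id", i))
    }
    if (parts[1] %in% names(out)) {
      abort(paste0("duplicate drug id in fingerprint file: ", parts[1]))
    }
    out[[parts[1]]] <- sort(unique(feats))
  }
  out
}

#' Write a fingerprint table
#'
#' @param fingerprints Named list of integer feature-id vectors.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_fingerprints <- function(fingerprints, path) {
  writeLines(sprintf("%s\t%s", names(fingerprints),
                     vapply(fingerprints, function(f)
                       paste(sort(f), collapse = ","), character(1))),
             path)
  invisible(path)
}

#' Tanimoto (Jaccard) coefficient of two fingerprints
#'
#' @param a,b Integer feature-id vectors (non-empty sets).
#' @return `|A intersect B| / |A union B|`, in [0, 1].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    abort("tanimoto coefficient undefined for an empty feature set")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Similarity distributions within vs outside enriched clusters
#'
#' Compares a pairwise similarity (expression Pearson correlation or
#' chemical Tanimoto coefficient) between drug pairs inside enriched
#' clusters and pairs straddling the enriched / non-enriched boundary.
#' "Within" pairs have both members in the same enriched cluster (or, with
#' `within = "pooled"`, in any enriched cluster); "between" pairs have
#' exactly one member in an enriched cluster. Group medians and a
#' Wilcoxon rank-sum p-value are reported.
#'
#' @param clustering An `ap_clustering` (level 0).
#' @param enriched_ids Exemplar ids of the enriched clusters.
#' @param pair_scorer Function of two item ids returning a similarity; see
#'   [pearson_pair_scorer()] and [tanimoto_pair_scorer()].
#' @param within `"cluster"` (default) restricts within-pairs to the same
#'   enriched cluster; `"pooled"` allows pairs across enriched clusters.
#' @return A tibble with columns `pair_type` (within / between), `item1`,
#'   `item2`, `value`; attributes `medians` (named numeric) and
#'   `rank_sum_p`.
#' @export
similarity_distributions <- function(clustering, enriched_ids, pair_scorer,
                                     within = c("cluster", "pooled")) {
  within <- match.arg(within)
  stopifnot(all(enriched_ids %in% clustering$exemplars))
  ids <- clustering$ids
  cl <- clustering$assignment[ids]
  in_enr <- cl %in% enriched_ids
  if (sum(in_enr) < 2 || sum(!in_enr) < 1) {
    abort("need at least 2 items in enriched clusters and 1 outside")
  }
  pairs <- t(utils::combn(ids, 2))
  c1 <- cl[pairs[, 1]]
  c2 <- cl[pairs[, 2]]
  e1 <- c1 %in% enriched_ids
  e2 <- c2 %in% enriched_ids
  is_within <- if (within == "cluster") e1 & e2 & c1 == c2 else e1 & e2
  is_between <- xor(e1, e2)
  keep <- is_within | is_between
  if (sum(is_within) < 1 || sum(is_between) < 1) {
    abort("fewer than one pair in a comparison group")
  }
  vals <- vapply(which(keep), function(i) {
    pair_scorer(pairs[i, 1], pairs[i, 2])
  }, numeric(1))
  out <- tibble(pair_type = ifelse(is_within[keep], "within", "between"),
                item1 = pairs[keep, 1], item2 = pairs[keep, 2],
                value = vals)
  out <- out[!is.na(out$value), ]
  w <- out$value[out$pair_type == "within"]
  b <- out$value[out$pair_type == "between"]
  if (length(w) < 2 || length(b) < 2) {
    abort("fewer than 2 scored pairs in a comparison group")
  }
  rs <- rank_sum_test(w, b)
  attr(out, "medians") <- c(within = median(w), between = median(b))
  attr(out, "rank_sum_p") <- rs$p_value
  out
}

#' Pair scorers for similarity distributions
#'
#' `pearson_pair_scorer()` looks pairs up in a precomputed expression
#' similarity matrix; `tanimoto_pair_scorer()` computes Tanimoto
#' coefficients from a fingerprint list, returning `NA` (with one logged
#' count at creation time) for drugs lacking fingerprints.
#'
#' @param sim A `herg_similarity` over the clustering's item ids.
#' @return A function of two item ids.
#' @export
pearson_pair_scorer <- function(sim) {
  S <- sim$S
  function(i, j) S[i, j]
}

#' @rdname pearson_pair_scorer
#' @param fingerprints Named list of feature-id vectors.
#' @param id_map Optional named vector translating item (profile) ids to
#'   fingerprint (drug) ids.
#' @export
tanimoto_pair_scorer <- function(fingerprints, id_map = NULL) {
  lookup <- function(i) {
    d <- if (is.null(id_map)) i else unname(id_map[i])
    fingerprints[[d]]
  }
  function(i, j) {
    a <- lookup(i)
    b <- lookup(j)
    if (is.null(a) || is.null(b)) return(NA_real_)
    tanimoto(a, b)
  }
}
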