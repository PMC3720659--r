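#' Label drugs for hERG inhibition from experimental and clinical sources
#'
#' A drug is labelled an inhibitor when it decreased hERG current by at
#' least `threshold` percent at 10 uM (an IC50 of roughly 10 uM or less),
#' or when it appears on a clinical LQT-risk drug list. The disjoint
#' reporting classes follow the convention that a drug counted as an
#' experimental blocker is excluded from the clinical (LQT) class even if
#' also listed.
#'
#' @param herg_table Tibble with columns `drug_id`, `pct_inhib_1uM`,
#'   `pct_inhib_10uM` (either percentage may be missing).
#' @param lqt_list Character vector of LQT-annotated drug ids.
#' @param threshold Percent-inhibition threshold at 10 uM (default 50).
#' @param all_drugs Optional character vector of every drug in the study;
#'   drugs absent from both sources are labelled `"untested"`.
#' @return A tibble with columns `drug_id`, `pct_inhib_1uM`,
#'   `pct_inhib_10uM`, `lqt_flag`, `label` (inhibitor / negative /
#'   untested) and `class` (experimental / lqt / negative / untested).
#' @export
label_inhibitors <- function(herg_table, lqt_list = character(),
                             threshold = 50, all_drugs = NULL) {
  stopifnot(threshold > 0, threshold <= 100)
  herg_table <- as_tibble(herg_table)
  if (anyDuplicated(herg_table$drug_id)) {
    abort("duplicate drug_id in hERG annotation table")
  }
  out_of_range <- with(herg_table, !is.na(pct_inhib_10uM) &
                         (pct_inhib_10uM < -100 | pct_inhib_10uM > 200))
  if (any(out_of_range)) {
    warn(paste0("percent inhibition outside [-100, 200] for: ",
                paste(herg_table$drug_id[out_of_range], collapse = ", "),
                " (values kept)"))
  }
  drugs <- union(herg_table$drug_id, lqt_list)
  if (!is.null(all_drugs)) drugs <- union(drugs, all_drugs)
  ann <- tibble(drug_id = drugs) |>
    dplyr::left_join(herg_table, by = "drug_id") |>
    dplyr::mutate(lqt_flag = .data$drug_id %in% lqt_list)
  tested <- !is.na(ann$pct_inhib_10uM)
  experimental <- tested & ann$pct_inhib_10uM >= threshold
  ann$label <- dplyr::case_when(
    experimental | ann$lqt_flag ~ "inhibitor",
    tested | !is.na(ann$pct_inhib_1uM) ~ "negative",
    TRUE ~ "untested"
  )
  ann$class <- dplyr::case_when(
    experimental ~ "experimental",
    ann$lqt_flag ~ "lqt",
    ann$label == "negative" ~ "negative",
    TRUE ~ "untested"
  )
  ann
}

#' Exact hypergeometric enrichment test
#'
#' Tail probability of the hypergeometric distribution: drawing `n` items
#' from a population of `N` containing `K` successes, having observed `k`.
#' With `strict = FALSE` (default) the upper tail is \eqn{P(X \ge k)} and
#' the lower tail \eqn{P(X \le k)}; with `strict = TRUE` the observed
#' count is excluded (\eqn{P(X > k)} / \eqn{P(X < k)}), the exceedance
#' convention matching a permutation count of how often a random draw
#' exceeds the observation. Computed via the stable log-space tail of
#' [stats::phyper()].
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Sample size.
#' @param k Observed successes in the sample.
#' @param tail `"upper"` (enrichment) or `"lower"` (depletion).
#' @param strict Exclude the observed count from the tail (default FALSE).
#' @return The tail p-value.
#' @export
hypergeometric_test <- function(N, K, n, k, tail = c("upper", "lower"),
                                strict = FALSE) {
  tail <- match.arg(tail)
  if (K > N || n > N || k < 0 || k > min(n, K)) {
    abort("inconsistent hypergeometric counts: need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  if (tail == "upper") {
    q <- if (strict) k else k - 1
    exp(phyper(q, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  } else {
    q <- if (strict) k - 1 else k
    if (q < 0) return(0)
    exp(phyper(q, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
  }
}

#' Permutation test of cluster enrichment for annotated inhibitors
#'
#' For each cluster, the observed statistic is the fraction of inhibitors
#' among the cluster's annotated members. Inhibitor labels are then
#' randomly permuted over all annotated drugs (`n_perm` times, cluster
#' memberships fixed) and the empirical p-value is the proportion of
#' permutations whose cluster fraction is at least the observed one.
#' Zero counts are reported with a below-resolution flag (printed as
#' `"<1/n_perm"`). Benjamini-Hochberg adjustment at `fdr` flags the
#' significantly enriched clusters, and an exact hypergeometric upper-tail
#' p-value is reported alongside.
#'
#' @param clustering An `ap_clustering`, or a named vector mapping item id
#'   to cluster id.
#' @param labels Annotation tibble from [label_inhibitors()], or a named
#'   vector of labels (`inhibitor` / `negative` / `untested`) keyed by
#'   item id.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.2).
#' @param estimator `"count"` (default) uses the plain count/n_perm
#'   empirical p-value; `"add_one"` uses (count+1)/(n_perm+1).
#' @return A `herg_enrichment` tibble: one row per cluster with
#'   `cluster_id`, `n_members`, `n_annotated`, `n_inhibitors`, `fraction`,
#'   `empirical_p`, `below_resolution`, `p_display`, `bh_adjusted`,
#'   `bh_significant`, `hypergeom_p`.
#' @export
cluster_enrichment_permutation <- function(clustering, labels, n_perm = 1000,
                                           seed = 1L, fdr = 0.2,
                                           estimator = c("count", "add_one")) {
  estimator <- match.arg(estimator)
  assignment <- if (inherits(clustering, "ap_clustering")) {
    clustering$assignment
  } else clustering
  lab <- normalize_labels(labels, names(assignment))
  annotated <- names(lab)[lab != "untested"]
  if (length(annotated) == 0) abort("no annotated drug in the clustered set")
  is_inhib <- lab[annotated] == "inhibitor"
  cl_of <- assignment[annotated]
  clusters <- unique(unname(assignment))
  n_ann <- table(factor(cl_of, levels = clusters))
  n_inh <- tapply(is_inhib, factor(cl_of, levels = clusters), sum)
  n_inh[is.na(n_inh)] <- 0
  frac <- ifelse(n_ann > 0, n_inh / n_ann, NA_real_)

  K <- sum(is_inhib)
  N <- length(annotated)
  perm_counts <- with_seed(derive_seed(seed, "enrichment-perm"), {
    exceed <- numeric(length(clusters))
    cl_f <- factor(cl_of, levels = clusters)
    for (p in seq_len(n_perm)) {
      shuffled <- sample(is_inhib)
      pf <- tapply(shuffled, cl_f, sum)
      pf[is.na(pf)] <- 0
      pfrac <- ifelse(n_ann > 0, pf / n_ann, NA_real_)
      exceed <- exceed + as.numeric(!is.na(pfrac) & !is.na(frac) & pfrac >= frac)
    }
    exceed
  })
  emp_p <- if (estimator == "count") perm_counts / n_perm else
    (perm_counts + 1) / (n_perm + 1)
  below <- emp_p == 0
  emp_p_adj_input <- ifelse(below, 1 / n_perm, emp_p)
  emp_p_adj_input[n_ann == 0] <- 1
  hg <- vapply(seq_along(clusters), function(i) {
    if (n_ann[i] == 0) return(1)
    hypergeometric_test(N, K, as.integer(n_ann[i]), as.integer(n_inh[i]),
                        tail = "upper")
  }, numeric(1))
  bh <- bh_adjust(emp_p_adj_input, fdr = fdr)
  out <- tibble(
    cluster_id = clusters,
    n_members = as.integer(table(factor(unname(assignment), levels = clusters))),
    n_annotated = as.integer(n_ann),
    n_inhibitors = as.integer(n_inh),
    fraction = as.numeric(frac),
    empirical_p = as.numeric(ifelse(n_ann == 0, 1, emp_p)),
    below_resolution = as.logical(below & n_ann > 0),
    p_display = as.character(ifelse(n_ann == 0, "1",
                                    ifelse(below, sprintf("<%g", 1 / n_perm),
                                           sprintf("%g", emp_p)))),
    bh_adjusted = as.numeric(bh$adjusted),
    bh_significant = as.logical(bh$significant & n_ann > 0),
    hypergeom_p = hg
  )
  class(out) <- c("herg_enrichment", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "fdr") <- fdr
  out
}

normalize_labels <- function(labels, item_ids) {
  if (is.data.frame(labels)) {
    lab <- setNames(labels$label, labels$drug_id)
  } else {
    lab <- labels
  }
  full <- setNames(rep("untested", length(item_ids)), item_ids)
  known <- intersect(names(lab), item_ids)
  full[known] <- lab[known]
  full
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Flags hypotheses significant at the given false discovery rate via the
#' step-up rule (largest i with p_(i) <= (i/m) * fdr), and returns the
#' standard BH-adjusted p-values.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param fdr Target false discovery rate (default 0.2).
#' @return List with `significant` (logical) and `adjusted` (numeric).
#' @export
bh_adjust <- function(p_values, fdr = 0.2) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adjusted <- p.adjust(p_values, method = "BH")
  list(significant = adjusted <= fdr, adjusted = adjusted)
}

#' Prediction statistics from enriched-cluster membership
#'
#' Treats membership in an enriched cluster as a positive hERG-inhibition
#' call. True positives are annotated inhibitors in enriched clusters,
#' false positives annotated non-inhibitors in enriched clusters, false
#' negatives inhibitors outside, true negatives non-inhibitors outside;
#' untested drugs are excluded throughout.
#'
#' @param clustering An `ap_clustering` or named item -> cluster vector.
#' @param enriched_ids Enriched cluster (exemplar) ids.
#' @param labels Annotation tibble or named label vector (see
#'   [cluster_enrichment_permutation()]).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `accuracy` (proportions in [0, 1]).
#' @export
prediction_stats <- function(clustering, enriched_ids, labels) {
  assignment <- if (inherits(clustering, "ap_clustering")) {
    clustering$assignment
  } else clustering
  lab <- normalize_labels(labels, names(assignment))
  annotated <- names(lab)[lab != "untested"]
  inh <- lab[annotated] == "inhibitor"
  in_enr <- assignment[annotated] %in% enriched_ids
  tp <- sum(inh & in_enr)
  fp <- sum(!inh & in_enr)
  fn <- sum(inh & !in_enr)
  tn <- sum(!inh & !in_enr)
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    accuracy = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else NA_real_
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum comparison of two samples: exact enumeration for
#' small tie-free samples, normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `statistic` (Mann-Whitney U) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
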