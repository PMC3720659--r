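#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an affinity-propagation clustering
#'
#' @param x An `ap_clustering`.
#' @param ... Unused.
#' @return A tibble with one row per item: `item`, `cluster` (exemplar
#'   id), `weight` (similarity to the exemplar), `is_exemplar`.
#' @export
tidy.ap_clustering <- function(x, ...) {
  tibble(item = x$ids,
         cluster = unname(x$assignment[x$ids]),
         weight = unname(x$weight[x$ids]),
         is_exemplar = x$ids %in% x$exemplars)
}

#' @rdname tidy.ap_clustering
#' @return For `glance()`: a one-row tibble with `n_items`, `n_clusters`,
#'   `preference`, `net_similarity`, `n_iterations`, `converged`.
#' @export
glance.ap_clustering <- function(x, ...) {
  tibble(n_items = length(x$ids),
         n_clusters = length(x$exemplars),
         preference = x$preference,
         net_similarity = x$net_similarity,
         n_iterations = x$n_iterations,
         converged = x$converged)
}

#' Tidy a cluster hierarchy
#'
#' @param x A `herg_hierarchy`.
#' @param ... Unused.
#' @return A tibble with one row per (level, item): `level`, `item`,
#'   `cluster`, `weight`, `is_exemplar`.
#' @export
tidy.herg_hierarchy <- function(x, ...) {
  purrr::imap_dfr(x$levels, function(cl, lvl) {
    dplyr::mutate(tidy(cl), level = lvl - 1L, .before = 1)
  })
}

#' @rdname tidy.herg_hierarchy
#' @export
glance.herg_hierarchy <- function(x, ...) {
  tibble(n_levels = length(x$levels),
         n_items = length(x$levels[[1]]$ids),
         n_level0_clusters = length(x$levels[[1]]$exemplars),
         n_top_clusters = length(x$levels[[length(x$levels)]]$exemplars),
         preference = x$preference)
}

#' Glance at a pipeline result
#'
#' @param x A `herg_pipeline_result`.
#' @param ... Unused.
#' @return One-row tibble of headline quantities: profile and cluster
#'   counts, enriched clusters, sensitivity/specificity/accuracy.
#' @export
glance.herg_pipeline_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_profiles = ncol(x$profiles$values),
           n_clusters = length(x$hierarchy$levels[[1]]$exemplars),
           n_enriched = length(x$enriched_ids)),
    x$prediction
  )
}
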