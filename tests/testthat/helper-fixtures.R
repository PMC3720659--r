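# Shared fixtures and small oracles, all built in code at test time.

# Reduced-scale generator settings for unit tests.
small_config <- function(...) {
  defaults <- list(
    n_probesets = 300, n_cell_lines = 2, n_batches_per_cell_line = 2,
    batch_size_range = c(26L, 80L), n_drugs = 60, n_replicates_per_drug = 2,
    concentrations = c(1, 10), off_mode_fraction = 0.2,
    n_planted_clusters = 2, planted_cluster_size = 10, signature_size = 30,
    silent_fraction = 0.2, vehicles_per_batch = 5
  )
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Build a compendium from a bare value matrix and minimal metadata fields.
mk_compendium <- function(values, batch_id, vehicle = NULL, drug_id = NULL,
                          cell_line = "A", concentration = 1,
                          platform_id = "P1") {
  n <- ncol(values)
  colnames(values) <- sprintf("a%02d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(vehicle)) vehicle <- rep(FALSE, n)
  if (is.null(drug_id)) drug_id <- ifelse(vehicle, "VEHICLE", sprintf("d%02d", seq_len(n)))
  new_compendium(values, tibble::tibble(
    array_id = colnames(values), drug_id = drug_id,
    cell_line = rep_len(cell_line, n),
    concentration = rep_len(concentration, n),
    batch_id = rep_len(batch_id, n),
    vehicle = vehicle, platform_id = rep_len(platform_id, n)))
}

mk_profiles <- function(values, cell_line = "A", drug_id = NULL,
                        masked = FALSE) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("p%02d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(drug_id)) drug_id <- colnames(values)
  new_profiles(values, tibble::tibble(
    profile_id = colnames(values), drug_id = drug_id,
    cell_line = rep_len(cell_line, n)), masked = masked)
}

# Minimal clustering object for functions that only need an assignment.
fake_clustering <- function(assignment) {
  structure(list(ids = names(assignment),
                 exemplars = unique(unname(assignment)),
                 assignment = assignment,
                 weight = stats::setNames(rep(NA_real_, length(assignment)),
                                          names(assignment)),
                 n_iterations = 0L, converged = TRUE,
                 net_similarity = NA_real_, preference = NA_real_),
            class = "ap_clustering")
}

# Exhaustive oracle: best net similarity over every nonempty exemplar subset.
brute_force_best <- function(sim) {
  n <- length(sim$ids)
  stopifnot(n <= 14)
  best <- -Inf
  for (m in seq_len(2^n - 1)) {
    ex <- sim$ids[as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))]
    v <- net_similarity(sim, ex)
    if (v > best) best <- v
  }
  best
}

# One reduced-scale end-to-end run, cached across tests.
.fixture_cache <- new.env(parent = emptyenv())
small_pipeline <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    cfg <- pipeline_config(seed = 7, n_perm = 500, n_sets = 500)
    .fixture_cache$pipeline <- suppressMessages(
      run_pipeline(cfg, generator = small_config()))
    .fixture_cache$annotations_in <- generate_annotations(
      .fixture_cache$pipeline$truth, small_config(), seed = 7)
  }
  .fixture_cache$pipeline
}
small_annotations <- function() {
  small_pipeline()
  .fixture_cache$annotations_in
}
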