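#' Read an expression matrix and array metadata from TSV
#'
#' The matrix TSV has probeset ids in the first column and one column per
#' array; the metadata TSV has one row per array with the columns required
#' by [new_compendium()].
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A `herg_compendium`.
#' @export
read_expression <- function(matrix_path, metadata_path) {
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            array_id = readr::col_character(),
                            drug_id = readr::col_character(),
                            cell_line = readr::col_character(),
                            concentration = readr::col_double(),
                            batch_id = readr::col_character(),
                            vehicle = readr::col_logical(),
                            platform_id = readr::col_character()))
  ids <- mat_df[[1]]
  values <- as.matrix(mat_df[, -1])
  if (!is.numeric(values)) {
    bad <- which(!vapply(mat_df[-1], is.numeric, logical(1)))
    abort(paste0("non-numeric expression column(s): ",
                 paste(names(mat_df[-1])[bad], collapse = ", ")))
  }
  rownames(values) <- ids
  missing <- setdiff(colnames(values), meta$array_id)
  if (length(missing) > 0) {
    abort(paste0("arrays in matrix but absent from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  new_compendium(values, meta[meta$array_id %in% colnames(values), ])
}

#' Write an expression compendium to TSV
#'
#' @param c A `herg_compendium`.
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(c, matrix_path, metadata_path) {
  df <- dplyr::bind_cols(tibble(probeset_id = rownames(c$values)),
                         as_tibble(c$values))
  readr::write_tsv(df, matrix_path)
  readr::write_tsv(c$metadata, metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Read hERG annotation and LQT list files
#'
#' The annotation TSV has columns `drug_id`, `pct_inhib_1uM`,
#' `pct_inhib_10uM` (empty field = missing); the LQT list holds one drug
#' id per line.
#'
#' @param path File path.
#' @return A tibble (annotations) or character vector (LQT list).
#' @export
read_herg_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    drug_id = readr::col_character(),
                    pct_inhib_1uM = readr::col_double(),
                    pct_inhib_10uM = readr::col_double()))
}

#' @rdname read_herg_table
#' @export
read_lqt_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Pipeline configuration
#'
#' Collects every threshold and default of the analysis pipeline; unknown
#' fields are rejected and all values validated.
#'
#' @param ... Named overrides of the defaults (see source for the list:
#'   `platform_id`, `min_batch_size`, `fc_thresh`, `n_thresh`, `up_thresh`,
#'   `lower_pct`, `upper_pct`, `inhibitor_threshold`, `damping`,
#'   `max_iter`, `conv_iter`, `n_perm`, `fdr`, `validation_set_size`,
#'   `n_sets`, `seed`).
#' @return A validated list of class `herg_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    platform_id = "SYNTH-1",
    min_batch_size = 25,
    fc_thresh = 2,
    n_thresh = 10,
    up_thresh = 3,
    lower_pct = 2.5,
    upper_pct = 97.5,
    inhibitor_threshold = 50,
    damping = 0.9,
    max_iter = 1000,
    conv_iter = 50,
    n_perm = 1000,
    fdr = 0.2,
    validation_set_size = 4,
    n_sets = 1000,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides)
  stopifnot(cfg$min_batch_size >= 1, cfg$fc_thresh > 0, cfg$n_thresh >= 1,
            cfg$up_thresh > 0, cfg$lower_pct >= 0, cfg$upper_pct <= 100,
            cfg$lower_pct < cfg$upper_pct,
            cfg$inhibitor_threshold > 0, cfg$inhibitor_threshold <= 100,
            cfg$damping >= 0.5, cfg$damping < 1,
            cfg$max_iter >= 1, cfg$conv_iter >= 1,
            cfg$n_perm >= 1, cfg$fdr >= 0, cfg$fdr <= 1,
            cfg$validation_set_size >= 1, cfg$n_sets >= 1)
  structure(cfg, class = "herg_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (platform/batch selection, mode-concentration
#' selection, batch mean-centering, silent-drug filtering,
#' differential-expression masking, replicate merging), pooled
#' affinity-propagation clustering with hierarchical exemplar merging,
#' annotation, permutation enrichment with BH control, prediction
#' statistics and network export, in that fixed order.
#'
#' @param config A [pipeline_config()].
#' @param compendium A `herg_compendium`, or `NULL` with
#'   `generator = generator_config(...)` to simulate one.
#' @param herg_table,lqt_list Annotation inputs ([read_herg_table()] /
#'   [read_lqt_list()]); generated when simulating.
#' @param generator Optional [generator_config()] for simulate mode.
#' @param out_dir Optional directory: results, network files and a
#'   manifest JSON are written there.
#' @return A list of class `herg_pipeline_result` with elements `report`
#'   (processing statistics), `hierarchy`, `enrichment`, `enriched_ids`,
#'   `prediction`, `network`, `profiles`, `annotations`, `config`, and
#'   `truth` (simulate mode only).
#' @export
run_pipeline <- function(config = pipeline_config(), compendium = NULL,
                         herg_table = NULL, lqt_list = character(),
                         generator = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "herg_pipeline_config"))
  truth <- NULL
  if (is.null(compendium)) {
    if (is.null(generator)) generator <- generator_config()
    sim <- generate_compendium(generator, seed = config$seed)
    compendium <- sim$compendium
    truth <- sim$truth
    ann_in <- generate_annotations(sim$truth, generator, seed = config$seed)
    herg_table <- ann_in$herg_table
    lqt_list <- ann_in$lqt_list
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  all_drugs <- unique(compendium$metadata$drug_id[!compendium$metadata$vehicle])
  annotations <- stage("annotate", label_inhibitors(
    herg_table, lqt_list, threshold = config$inhibitor_threshold,
    all_drugs = all_drugs))

  snapshots <- list(input = compendium)
  selected <- stage("select_arrays", select_arrays(
    compendium, config$platform_id, config$min_batch_size))
  selected <- stage("select_mode_concentration", select_mode_concentration(selected))
  snapshots$batch_selected <- selected
  centered <- stage("batch_center", batch_center(selected))
  silent <- stage("filter_silent", filter_silent(
    centered$profiles, config$fc_thresh, config$n_thresh, config$up_thresh))
  snapshots$non_silent <- silent$kept
  masked <- stage("de_mask", de_mask(
    silent$kept, centered$controls, config$lower_pct, config$upper_pct))
  merged <- stage("merge_replicates", merge_replicates(masked))
  snapshots$merged <- merged
  report <- processing_report(snapshots, annotations)

  hierarchy <- stage("cluster", recursive_cluster(
    merged, damping = config$damping, max_iter = config$max_iter,
    conv_iter = config$conv_iter, seed = config$seed))
  level0 <- hierarchy$levels[[1]]

  labels <- setNames(annotations$label[match(merged$info$drug_id,
                                             annotations$drug_id)],
                     merged$info$profile_id)
  labels[is.na(labels)] <- "untested"
  enrichment <- stage("enrich", cluster_enrichment_permutation(
    level0, labels, n_perm = config$n_perm, seed = config$seed,
    fdr = config$fdr))
  enriched_ids <- enrichment$cluster_id[enrichment$bh_significant]
  prediction <- stage("predict", prediction_stats(level0, enriched_ids, labels))
  network <- stage("export", export_network(
    hierarchy,
    annotations = tibble(drug_id = merged$info$drug_id,
                         class = annotations$class[match(merged$info$drug_id,
                                                         annotations$drug_id)]) |>
      dplyr::distinct(),
    enriched_ids = enriched_ids))

  result <- structure(list(
    report = report, hierarchy = hierarchy, enrichment = enrichment,
    enriched_ids = enriched_ids, prediction = prediction, network = network,
    profiles = merged, annotations = annotations, removed_silent = silent$removed_ids,
    config = config, truth = truth), class = "herg_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(report, file.path(out_dir, "processing_report.tsv"))
    readr::write_tsv(as_tibble(enrichment), file.path(out_dir, "enrichment.tsv"))
    readr::write_tsv(prediction, file.path(out_dir, "prediction_stats.tsv"))
    write_network(network, file.path(out_dir, "network"))
    manifest <- list(config = unclass(config), seed = config$seed,
                     package_version = as.character(utils::packageVersion("hergnet")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  for (i in seq_len(nrow(report))) {
    inform(sprintf(
      "stage %-16s arrays=%5d drugs=%4d exp_inhib=%4d (%3d unique) lqt=%4d (%3d unique)",
      report$stage[i], report$n_arrays[i], report$n_unique_drugs[i],
      report$n_experimental[i], report$n_experimental_unique[i],
      report$n_lqt[i], report$n_lqt_unique[i]))
  }
  result
}

#' @export
print.herg_pipeline_result <- function(x, ...) {
  cat("<herg_pipeline_result>\n")
  cat("  profiles: ", ncol(x$profiles$values), " merged (drug, cell line) pairs\n",
      sep = "")
  cat("  clusters: ", length(x$hierarchy$levels[[1]]$exemplars),
      " at level 0 across ", length(x$hierarchy$levels), " level(s)\n", sep = "")
  cat("  enriched clusters (BH, fdr=", attr(x$enrichment, "fdr"), "): ",
      length(x$enriched_ids), "\n", sep = "")
  p <- x$prediction
  cat(sprintf("  prediction: sens %.0f%% spec %.0f%% acc %.0f%% (TP=%d TN=%d FP=%d FN=%d)\n",
              100 * p$sensitivity, 100 * p$specificity, 100 * p$accuracy,
              p$tp, p$tn, p$fp, p$fn))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between an inferred clustering and a reference partition,
#' corrected for chance.
#'
#' @param inferred,reference Vectors of cluster labels over the same items
#'   (matched by names when both are named).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(inferred, reference) {
  if (!is.null(names(inferred)) && !is.null(names(reference))) {
    common <- intersect(names(inferred), names(reference))
    inferred <- inferred[common]
    reference <- reference[common]
  }
  stopifnot(length(inferred) == length(reference))
  mclust::adjustedRandIndex(as.character(inferred), as.character(reference))
}

#' Ground-truth partition for clustering evaluation
#'
#' Builds the reference labelling used to score recovery of planted
#' structure: profiles of drugs in a planted cluster share that cluster's
#' label; every background drug is its own singleton.
#'
#' @param profile_ids Profile ids (format `drug@cell`) or drug ids.
#' @param truth Ground-truth list from [generate_compendium()].
#' @return Named character vector of reference labels.
#' @export
truth_partition <- function(profile_ids, truth) {
  drug <- sub("@.*$", "", profile_ids)
  ref <- truth$true_cluster[drug]
  bg <- ref == "background"
  ref[bg] <- paste0("bg_", drug[bg])
  setNames(unname(ref), profile_ids)
}
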