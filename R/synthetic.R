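#' Configuration for the synthetic compendium generator
#'
#' Builds and validates the parameter set for [generate_compendium()]. The
#' defaults describe a desk-scale analogue of a drug-treatment expression
#' compendium: several hundred drugs profiled in triplicate cell lines in
#' moderately sized experimental batches with DMSO vehicle controls, a
#' handful of planted clusters of correlated transcriptional responses (one
#' of them enriched for hERG inhibitors), a transcriptionally silent drug
#' subpopulation, and per-drug hERG annotation coverage with gaps.
#'
#' @param n_probesets Number of probesets (matrix rows).
#' @param n_cell_lines Number of cell lines; drugs are assigned round-robin.
#' @param n_batches_per_cell_line Experimental batches per cell line.
#' @param batch_size_range Length-2 integer vector; the implied mean batch
#'   size (drug plus vehicle arrays) must fall inside this range.
#' @param n_drugs Number of unique drugs.
#' @param n_replicates_per_drug Replicate treatment arrays per drug at its
#'   mode concentration.
#' @param concentrations Candidate test concentrations (micromolar); each
#'   drug receives one as its mode.
#' @param off_mode_fraction Fraction of drugs receiving one extra array at a
#'   non-mode concentration (exercises mode selection).
#' @param n_planted_clusters Number of planted response clusters. Cluster 1
#'   is the hERG-inhibitor-enriched cluster.
#' @param planted_cluster_size Drugs per planted cluster.
#' @param signature_size Probesets carrying each cluster (or background
#'   drug) signature.
#' @param signature_effect Log2 magnitude of signature probeset effects;
#'   must clear the silent-filter thresholds so planted actives survive.
#' @param noise_sd Iid Gaussian measurement noise, log2 units.
#' @param batch_effect_sd Sd of the per-batch additive offset vector.
#' @param silent_fraction Fraction of drugs that are transcriptionally
#'   silent (small-amplitude responses failing the silent filter).
#' @param silent_amplitude_sd Sd of the silent drugs' weak responses.
#' @param inhibitor_fraction_planted Probability that a cluster-1 drug is a
#'   true hERG inhibitor.
#' @param inhibitor_fraction_background Same probability for all other drugs.
#' @param untested_fraction Fraction of drugs absent from both annotation
#'   sources.
#' @param lqt_fraction Fraction of annotated true inhibitors also flagged
#'   for clinical LQT risk.
#' @param inhib_mean_pos,inhib_mean_neg,inhib_sd Percent-inhibition (10 uM)
#'   distribution parameters for true inhibitors and negatives.
#' @param vehicles_per_batch DMSO control arrays per batch.
#' @param n_offplatform_arrays Extra arrays emitted on a second platform id
#'   (exercises platform selection).
#' @param fingerprint_n_features,fingerprint_universe Features per random
#'   fingerprint and size of the feature-id universe.
#' @param seed Default master seed.
#' @return A validated list of class `herg_generator_config`.
#' @export
generator_config <- function(n_probesets = 1000,
                             n_cell_lines = 3,
                             n_batches_per_cell_line = 6,
                             batch_size_range = c(26L, 80L),
                             n_drugs = 300,
                             n_replicates_per_drug = 2,
                             concentrations = c(0.1, 1, 10),
                             off_mode_fraction = 0.2,
                             n_planted_clusters = 6,
                             planted_cluster_size = 25,
                             signature_size = 50,
                             signature_effect = 4,
                             noise_sd = 0.25,
                             batch_effect_sd = 1,
                             silent_fraction = 0.3,
                             silent_amplitude_sd = 0.3,
                             inhibitor_fraction_planted = 0.8,
                             inhibitor_fraction_background = 0.1,
                             untested_fraction = 0.3,
                             lqt_fraction = 0.3,
                             inhib_mean_pos = 80,
                             inhib_mean_neg = 5,
                             inhib_sd = 10,
                             vehicles_per_batch = 6,
                             n_offplatform_arrays = 0,
                             fingerprint_n_features = 30,
                             fingerprint_universe = 1024,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "herg_generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    abort(paste0("invalid generator configuration: `", field, "` ", why))
  }
  counts <- c("n_probesets", "n_cell_lines", "n_batches_per_cell_line",
              "n_drugs", "n_replicates_per_drug", "n_planted_clusters",
              "planted_cluster_size", "signature_size", "vehicles_per_batch",
              "fingerprint_n_features", "fingerprint_universe")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != floor(v))
      bad(f, "must be a non-negative integer count")
  }
  props <- c("silent_fraction", "inhibitor_fraction_planted",
             "inhibitor_fraction_background", "untested_fraction",
             "lqt_fraction", "off_mode_fraction")
  for (f in props) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      bad(f, "must be a proportion in [0, 1]")
  }
  if (cfg$signature_size > cfg$n_probesets)
    bad("signature_size", "exceeds n_probesets")
  if (cfg$n_planted_clusters * cfg$signature_size > cfg$n_probesets)
    bad("signature_size", "x n_planted_clusters exceeds n_probesets")
  if (cfg$n_planted_clusters * cfg$planted_cluster_size > cfg$n_drugs)
    bad("planted_cluster_size", "x n_planted_clusters exceeds n_drugs")
  if (cfg$signature_effect < 3)
    bad("signature_effect", "must be >= 3 so active drugs clear the silent-filter thresholds")
  if (cfg$n_planted_clusters > 0 && cfg$signature_size < 10)
    bad("signature_size", "must be >= 10 so active drugs clear the silent-filter count threshold")
  if (length(cfg$batch_size_range) != 2 ||
      cfg$batch_size_range[1] > cfg$batch_size_range[2])
    bad("batch_size_range", "must be an increasing (min, max) pair")
  if (length(cfg$concentrations) < 1 || any(cfg$concentrations <= 0))
    bad("concentrations", "must be positive micromolar values")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be non-negative")
  if (cfg$batch_effect_sd < 0) bad("batch_effect_sd", "must be non-negative")
  n_silent <- round(cfg$silent_fraction * cfg$n_drugs)
  n_background <- cfg$n_drugs - cfg$n_planted_clusters * cfg$planted_cluster_size
  if (n_silent > n_background)
    bad("silent_fraction", "implies more silent drugs than background (non-planted) drugs")
  mean_batch <- cfg$n_drugs / cfg$n_cell_lines *
    (cfg$n_replicates_per_drug + cfg$off_mode_fraction) /
    cfg$n_batches_per_cell_line + cfg$vehicles_per_batch
  if (mean_batch < cfg$batch_size_range[1] || mean_batch > cfg$batch_size_range[2])
    bad("batch_size_range", sprintf(
      "does not contain the implied mean batch size (%.1f arrays)", mean_batch))
  cfg
}

#' Generate a synthetic drug-treatment expression compendium
#'
#' Simulates a log2 expression compendium with known ground truth. Each
#' array is baseline + per-batch additive offset + the drug's response
#' signature (planted-cluster, individual, or weak/silent) + iid Gaussian
#' noise; vehicle arrays carry only baseline, batch effect and noise.
#' All outputs are pure functions of `(config, seed)`.
#'
#' @param config A [generator_config()] object.
#' @param seed Integer master seed; defaults to `config$seed`.
#' @return A list with elements `compendium` (a [new_compendium()]) and
#'   `truth`, a list with `true_cluster` (named vector: cluster id or
#'   `"background"`), `silent_set`, `true_label` (named vector in
#'   {inhibitor, negative, untested}), and `signature_probesets` (named
#'   list of signed log2 effects by probeset id, one per planted cluster).
#' @export
generate_compendium <- function(config, seed = config$seed) {
  config <- validate_generator_config(config)
  with_seed(derive_seed(seed, "compendium"), {
    n_drugs <- config$n_drugs
    drugs <- sprintf("drug%03d", seq_len(n_drugs))
    probesets <- sprintf("ps%04d", seq_len(config$n_probesets))
    cells <- sprintf("CL%d", seq_len(config$n_cell_lines))

    # --- ground-truth partition -------------------------------------------
    shuffled <- sample(drugs)
    n_planted <- config$n_planted_clusters * config$planted_cluster_size
    true_cluster <- setNames(rep("background", n_drugs), drugs)
    if (config$n_planted_clusters > 0) {
      planted <- shuffled[seq_len(n_planted)]
      true_cluster[planted] <- rep(sprintf("C%d", seq_len(config$n_planted_clusters)),
                                   each = config$planted_cluster_size)
    }
    background <- shuffled[setdiff(seq_len(n_drugs), seq_len(n_planted))]
    silent_set <- sort(sample(background, round(config$silent_fraction * n_drugs)))

    # --- inhibitor / annotation-coverage truth ----------------------------
    untested <- runif(n_drugs) < config$untested_fraction
    p_inhib <- ifelse(true_cluster[drugs] == "C1",
                      config$inhibitor_fraction_planted,
                      config$inhibitor_fraction_background)
    inhib <- runif(n_drugs) < p_inhib
    true_label <- setNames(ifelse(untested, "untested",
                                  ifelse(inhib, "inhibitor", "negative")), drugs)

    # --- response signatures ----------------------------------------------
    sig_pool <- sample(probesets)
    signature_probesets <- list()
    responses <- matrix(0, config$n_probesets, n_drugs,
                        dimnames = list(probesets, drugs))
    make_effects <- function(ids) {
      k <- length(ids)
      sgn <- rep(c(1, -1), times = c(ceiling(0.6 * k), k - ceiling(0.6 * k)))
      setNames(sgn[sample(k)] * config$signature_effect, ids)
    }
    if (config$n_planted_clusters > 0) {
      for (j in seq_len(config$n_planted_clusters)) {
        ids <- sig_pool[((j - 1) * config$signature_size + 1):(j * config$signature_size)]
        eff <- make_effects(ids)
        signature_probesets[[sprintf("C%d", j)]] <- eff
        members <- drugs[true_cluster == sprintf("C%d", j)]
        responses[ids, members] <- eff
      }
    }
    for (d in setdiff(background, silent_set)) {
      ids <- sample(probesets, config$signature_size)
      responses[ids, d] <- make_effects(ids)
    }

    # --- array layout ------------------------------------------------------
    cell_of <- setNames(cells[(seq_len(n_drugs) - 1) %% config$n_cell_lines + 1],
                        shuffled)
    mode_conc <- setNames(sample(config$concentrations, n_drugs, replace = TRUE),
                          drugs)
    meta <- purrr::map_dfr(drugs, function(d) {
      conc <- rep(mode_conc[[d]], config$n_replicates_per_drug)
      if (length(config$concentrations) > 1 &&
          runif(1) < config$off_mode_fraction) {
        conc <- c(conc, sample(setdiff(config$concentrations, mode_conc[[d]]), 1))
      }
      tibble(drug_id = d, cell_line = cell_of[[d]], concentration = conc,
             vehicle = FALSE)
    })
    # deal each cell line's arrays into batches round-robin after a shuffle
    meta$batch_id <- NA_character_
    for (cl in cells) {
      idx <- sample(which(meta$cell_line == cl))
      meta$batch_id[idx] <- sprintf("%s_B%d", cl,
                                    (seq_along(idx) - 1) %% config$n_batches_per_cell_line + 1)
    }
    veh <- tidyr::expand_grid(
      cell_line = cells,
      b = seq_len(config$n_batches_per_cell_line),
      r = seq_len(config$vehicles_per_batch)
    )
    veh <- tibble(drug_id = "VEHICLE", cell_line = veh$cell_line,
                  concentration = 0,
                  vehicle = TRUE,
                  batch_id = sprintf("%s_B%d", veh$cell_line, veh$b))
    meta <- dplyr::bind_rows(meta, veh)
    meta$platform_id <- "SYNTH-1"
    if (config$n_offplatform_arrays > 0) {
      off <- meta[sample(which(!meta$vehicle),
                         min(config$n_offplatform_arrays, sum(!meta$vehicle))), ]
      off$platform_id <- "SYNTH-2"
      meta <- dplyr::bind_rows(meta, off)
    }
    meta$array_id <- sprintf("arr%04d", seq_len(nrow(meta)))
    meta <- meta[, c("array_id", "drug_id", "cell_line", "concentration",
                     "batch_id", "vehicle", "platform_id")]

    # --- expression values -------------------------------------------------
    baseline <- rnorm(config$n_probesets, 7, 1)
    batches <- unique(meta$batch_id)
    batch_eff <- matrix(rnorm(config$n_probesets * length(batches),
                              0, config$batch_effect_sd),
                        config$n_probesets, length(batches),
                        dimnames = list(probesets, batches))
    values <- baseline +
      batch_eff[, meta$batch_id, drop = FALSE] +
      matrix(rnorm(config$n_probesets * nrow(meta), 0, config$noise_sd),
             config$n_probesets, nrow(meta))
    drug_cols <- !meta$vehicle
    values[, drug_cols] <- values[, drug_cols] +
      responses[, meta$drug_id[drug_cols], drop = FALSE]
    # silent drugs respond weakly and irreproducibly: independent
    # small-amplitude draws per array, so replicate pairs are uncorrelated
    silent_cols <- which(drug_cols & meta$drug_id %in% silent_set)
    if (length(silent_cols) > 0) {
      values[, silent_cols] <- values[, silent_cols] +
        matrix(rnorm(config$n_probesets * length(silent_cols),
                     0, config$silent_amplitude_sd),
               config$n_probesets, length(silent_cols))
    }
    colnames(values) <- meta$array_id
    rownames(values) <- probesets

    list(
      compendium = new_compendium(values, meta),
      truth = list(true_cluster = true_cluster,
                   silent_set = silent_set,
                   true_label = true_label,
                   signature_probesets = signature_probesets)
    )
  })
}

#' Generate synthetic hERG annotations, LQT list and fingerprints
#'
#' Draws percent hERG-inhibition measurements for annotated drugs from the
#' configured inhibitor/negative distributions, flags a subset of true
#' inhibitors for clinical LQT risk (some carrying only the clinical flag,
#' with no electrophysiology record), and assigns every drug a random
#' fingerprint feature set statistically independent of cluster membership,
#' so chemical similarity carries no information about the planted
#' expression clusters.
#'
#' @param truth Ground-truth list from [generate_compendium()].
#' @param config The [generator_config()] used to generate it.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `herg_table` (tibble: drug_id, pct_inhib_1uM,
#'   pct_inhib_10uM), `lqt_list` (character vector of drug ids) and
#'   `fingerprints` (named list of sorted integer feature-id vectors).
#' @export
generate_annotations <- function(truth, config, seed = config$seed) {
  config <- validate_generator_config(config)
  drugs <- names(truth$true_label)
  if (is.null(drugs) || anyDuplicated(drugs) ||
      !setequal(drugs, names(truth$true_cluster))) {
    abort("ground truth is inconsistent: true_label and true_cluster must cover the same drug ids")
  }
  with_seed(derive_seed(seed, "annotations"), {
    label <- truth$true_label
    annotated <- drugs[label != "untested"]
    is_inhib <- label[annotated] == "inhibitor"
    pct10 <- ifelse(is_inhib,
                    rnorm(length(annotated), config$inhib_mean_pos, config$inhib_sd),
                    rnorm(length(annotated), config$inhib_mean_neg, config$inhib_sd))
    pct1 <- 0.4 * pct10 + rnorm(length(annotated), 0, config$inhib_sd / 2)
    herg_table <- tibble(drug_id = annotated,
                         pct_inhib_1uM = pct1,
                         pct_inhib_10uM = pct10)
    inhibitors <- annotated[is_inhib]
    lqt_list <- sort(sample(inhibitors,
                            round(config$lqt_fraction * length(inhibitors))))
    # half of the LQT drugs are clinical-only: no electrophysiology record,
    # so their inhibitor label must come from the LQT list alone
    clinical_only <- lqt_list[seq_len(floor(length(lqt_list) / 2))]
    herg_table <- herg_table[!herg_table$drug_id %in% clinical_only, ]
    fingerprints <- lapply(setNames(drugs, drugs), function(d) {
      sort(sample.int(config$fingerprint_universe, config$fingerprint_n_features))
    })
    list(herg_table = herg_table, lqt_list = lqt_list,
         fingerprints = fingerprints)
  })
}
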