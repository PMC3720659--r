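#' Select arrays by platform and batch size
#'
#' Retains arrays measured on one platform and belonging to batches with
#' strictly more than `min_batch_size` arrays (drug and vehicle alike), so
#' that the batch mean is a stable estimate of the vehicle-level baseline.
#'
#' @param c A [new_compendium()] object.
#' @param platform_id Platform to keep.
#' @param min_batch_size Batches must have strictly more arrays than this
#'   (default 25).
#' @return A filtered `herg_compendium`.
#' @export
select_arrays <- function(c, platform_id, min_batch_size = 25) {
  stopifnot(min_batch_size >= 1)
  m <- c$metadata
  on_platform <- m$array_id[m$platform_id == platform_id]
  if (length(on_platform) == 0) {
    abort(paste0("no arrays on platform `", platform_id, "` (empty compendium)"))
  }
  m <- m[m$platform_id == platform_id, ]
  sizes <- table(m$batch_id)
  keep_batches <- names(sizes)[sizes > min_batch_size]
  keep <- m$array_id[m$batch_id %in% keep_batches]
  if (length(keep) == 0) {
    abort(paste0("no batch exceeds ", min_batch_size,
                 " arrays (empty compendium)"))
  }
  subset_arrays(c, keep)
}

#' Keep only each drug's modal test concentration
#'
#' For each (drug, cell line) pair, retains only the arrays measured at the
#' concentration with the most replicates (the mode); ties break to the
#' lowest tied concentration. Vehicle arrays are untouched.
#'
#' @param c A [new_compendium()] object.
#' @return A filtered `herg_compendium`.
#' @export
select_mode_concentration <- function(c) {
  m <- c$metadata
  drug_meta <- m[!m$vehicle, ]
  keep <- drug_meta |>
    dplyr::group_by(.data$drug_id, .data$cell_line) |>
    dplyr::group_modify(function(df, key) {
      counts <- table(df$concentration)
      top <- counts[counts == max(counts)]
      mode_conc <- min(as.numeric(names(top)))
      df[df$concentration == mode_conc, ]
    }) |>
    dplyr::ungroup()
  subset_arrays(c, c(keep$array_id, m$array_id[m$vehicle]))
}

#' Mean-center probesets within each experimental batch
#'
#' Subtracts, per probeset and batch, the mean over all arrays in the batch
#' (drug treatments and vehicle controls alike); the batch mean plays the
#' role of a vehicle-level reference, so the centered values are log2 fold
#' changes versus batch mean. The centered vehicle arrays are returned
#' separately for later differential-expression masking.
#'
#' @param c A [new_compendium()] object; every batch needs at least 2 arrays.
#' @return A list with `profiles` (centered drug arrays, [new_profiles()])
#'   and `controls` (centered vehicle arrays, `herg_profiles` with
#'   `drug_id = "VEHICLE"`).
#' @export
batch_center <- function(c) {
  m <- c$metadata
  sizes <- table(m$batch_id)
  if (any(sizes < 2)) {
    abort(paste0("cannot mean-center batches with a single array: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  centered <- c$values
  for (b in names(sizes)) {
    cols <- m$array_id[m$batch_id == b]
    centered[, cols] <- c$values[, cols, drop = FALSE] -
      rowMeans(c$values[, cols, drop = FALSE])
  }
  info <- tibble(profile_id = m$array_id, drug_id = m$drug_id,
                 cell_line = m$cell_line, concentration = m$concentration,
                 batch_id = m$batch_id)
  drug_cols <- m$array_id[!m$vehicle]
  veh_cols <- m$array_id[m$vehicle]
  list(
    profiles = new_profiles(centered[, drug_cols, drop = FALSE],
                            info[match(drug_cols, info$profile_id), ]),
    controls = new_profiles(centered[, veh_cols, drop = FALSE],
                            info[match(veh_cols, info$profile_id), ])
  )
}

#' Filter transcriptionally silent treatment profiles
#'
#' A batch-centered array profile is kept only if it shows (i) at least
#' `n_thresh` probesets with absolute log2 fold change of at least
#' `fc_thresh`, and (ii) at least one probeset up-regulated by at least
#' `up_thresh` log2 units. Profiles failing the criterion represent
#' transcriptionally silent treatments whose apparent response is random
#' signal variation, and are removed before clustering.
#'
#' @param profiles Centered array profiles ([new_profiles()]).
#' @param fc_thresh Absolute log2 fold-change threshold (default 2).
#' @param n_thresh Minimum number of probesets at `fc_thresh` (default 10).
#' @param up_thresh Up-regulation log2 threshold (default 3).
#' @param rule `"both"` (default) keeps a profile only when both conditions
#'   hold; `"either"` keeps it when at least one does.
#' @return A list with `kept` (filtered `herg_profiles`) and `removed_ids`
#'   (tibble of removed profile ids with drug and cell line).
#' @export
filter_silent <- function(profiles, fc_thresh = 2, n_thresh = 10,
                          up_thresh = 3, rule = c("both", "either")) {
  rule <- match.arg(rule)
  v <- profiles$values
  n_fc <- colSums(abs(v) >= fc_thresh)
  any_up <- colSums(v >= up_thresh) >= 1
  ok <- if (rule == "both") (n_fc >= n_thresh) & any_up else
    (n_fc >= n_thresh) | any_up
  removed <- profiles$info[!ok, c("profile_id", "drug_id", "cell_line")]
  if (all(!ok)) abort("silent filter removed every profile")
  kept <- new_profiles(v[, ok, drop = FALSE], profiles$info[ok, ],
                       masked = profiles$masked)
  list(kept = kept, removed_ids = removed)
}

#' Mask probesets within the vehicle-control range
#'
#' Per cell line and probeset, computes the `lower_pct` and `upper_pct`
#' percentiles (linear interpolation between order statistics) of the
#' batch-centered DMSO control values, and sets to 0 every drug-treatment
#' value not outside that interval (boundary values inclusive). The
#' surviving nonzero values are the differentially expressed probesets of
#' each treatment.
#'
#' @param profiles Centered drug-array profiles.
#' @param controls Centered vehicle-control profiles ([batch_center()]).
#' @param lower_pct,upper_pct Percentile bounds (defaults 2.5 and 97.5).
#' @return The profiles with in-range values zeroed and `masked = TRUE`.
#' @export
de_mask <- function(profiles, controls, lower_pct = 2.5, upper_pct = 97.5) {
  v <- profiles$values
  for (cl in unique(profiles$info$cell_line)) {
    ctrl_cols <- controls$info$profile_id[controls$info$cell_line == cl]
    if (length(ctrl_cols) < 2) {
      abort(paste0("need at least 2 vehicle control arrays for cell line `",
                   cl, "`"))
    }
    ctrl <- controls$values[, ctrl_cols, drop = FALSE]
    lo <- apply(ctrl, 1, quantile, probs = lower_pct / 100, names = FALSE)
    hi <- apply(ctrl, 1, quantile, probs = upper_pct / 100, names = FALSE)
    cols <- profiles$info$profile_id[profiles$info$cell_line == cl]
    block <- v[, cols, drop = FALSE]
    inside <- block >= lo & block <= hi
    block[inside] <- 0
    v[, cols] <- block
  }
  new_profiles(v, profiles$info, masked = TRUE)
}

#' Average replicate profiles per drug and cell line
#'
#' Probeset values for replicate measurements of a given (drug, cell line)
#' pair are averaged into a single response profile.
#'
#' @param profiles Array-level profiles (all masked or all unmasked).
#' @return Merged `herg_profiles`, one column per unique (drug, cell line)
#'   pair, with `n_replicates_merged` recorded in the info tibble.
#' @export
merge_replicates <- function(profiles) {
  info <- profiles$info
  key <- paste(info$drug_id, info$cell_line, sep = "@")
  groups <- split(seq_len(nrow(info)), key)
  merged <- vapply(groups, function(idx) {
    rowMeans(profiles$values[, idx, drop = FALSE])
  }, numeric(nrow(profiles$values)))
  new_info <- tibble(
    profile_id = names(groups),
    drug_id = vapply(groups, function(idx) info$drug_id[idx[1]], character(1)),
    cell_line = vapply(groups, function(idx) info$cell_line[idx[1]], character(1)),
    n_replicates_merged = unname(lengths(groups))
  )
  new_profiles(merged, new_info, masked = profiles$masked)
}

#' Tabulate processing statistics per pipeline stage
#'
#' Counts arrays (or profiles), unique drugs, experimental-inhibitor and
#' LQT-drug instances at each snapshot of the preprocessing pipeline, in
#' the layout of a data-processing statistics table. Experimental and LQT
#' classes are disjoint: a drug counted as an experimental blocker is not
#' also counted in the LQT class.
#'
#' @param stage_snapshots Named list of `herg_compendium` or `herg_profiles`
#'   objects, in pipeline order.
#' @param annotations Annotation tibble from [label_inhibitors()].
#' @return A tibble with one row per stage.
#' @export
processing_report <- function(stage_snapshots, annotations) {
  exp_set <- annotations$drug_id[annotations$class == "experimental"]
  lqt_set <- annotations$drug_id[annotations$class == "lqt"]
  purrr::imap_dfr(stage_snapshots, function(x, stage) {
    meta <- if (inherits(x, "herg_compendium")) x$metadata else x$info
    drugs_all <- meta$drug_id[meta$drug_id != "VEHICLE"]
    tibble(
      stage = stage,
      n_arrays = length(drugs_all),
      n_unique_drugs = length(unique(drugs_all)),
      n_experimental = sum(drugs_all %in% exp_set),
      n_experimental_unique = length(unique(drugs_all[drugs_all %in% exp_set])),
      n_lqt = sum(drugs_all %in% lqt_set),
      n_lqt_unique = length(unique(drugs_all[drugs_all %in% lqt_set]))
    )
  })
}
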