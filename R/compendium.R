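#' Expression compendium container
#'
#' An expression compendium bundles a log2 intensity matrix (probesets in
#' rows, arrays in columns) with one metadata record per array. Vehicle
#' (DMSO) control arrays carry `drug_id = "VEHICLE"` and `vehicle = TRUE`.
#'
#' @param values Numeric matrix of log2 expression intensities, probesets x
#'   arrays, with row and column names.
#' @param metadata Data frame with one row per array and columns `array_id`,
#'   `drug_id`, `cell_line`, `concentration` (micromolar), `batch_id`,
#'   `vehicle` (logical), `platform_id`.
#' @return An object of class `herg_compendium`: a list with elements
#'   `values` and `metadata` (a tibble ordered as the matrix columns).
#' @export
new_compendium <- function(values, metadata) {
  metadata <- as_tibble(metadata)
  required <- c("array_id", "drug_id", "cell_line", "concentration",
                "batch_id", "vehicle", "platform_id")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (probesets x arrays)")
  }
  if (is.null(colnames(values))) abort("`values` must have array column names")
  if (nrow(metadata) != ncol(values)) {
    abort("metadata must have exactly one record per matrix column")
  }
  if (!setequal(metadata$array_id, colnames(values))) {
    extra <- setdiff(colnames(values), metadata$array_id)
    miss  <- setdiff(metadata$array_id, colnames(values))
    abort(paste0("array ids disagree between matrix and metadata; ",
                 "in matrix only: [", paste(extra, collapse = ", "),
                 "]; in metadata only: [", paste(miss, collapse = ", "), "]"))
  }
  if (anyDuplicated(metadata$array_id)) abort("duplicate array_id in metadata")
  if (any(!is.finite(values))) abort("expression values must all be finite")
  if (any(!nzchar(metadata$batch_id))) abort("batch_id must be nonempty")
  metadata <- metadata[match(colnames(values), metadata$array_id), ]
  structure(list(values = values, metadata = metadata),
            class = "herg_compendium")
}

#' @export
print.herg_compendium <- function(x, ...) {
  m <- x$metadata
  cat("<herg_compendium> ", nrow(x$values), " probesets x ",
      ncol(x$values), " arrays\n", sep = "")
  cat("  drugs: ", length(unique(m$drug_id[!m$vehicle])),
      " | vehicle arrays: ", sum(m$vehicle),
      " | cell lines: ", paste(unique(m$cell_line), collapse = ", "),
      " | batches: ", length(unique(m$batch_id)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.herg_compendium <- function(x) dim(x$values)

#' Subset a compendium by array ids
#'
#' @param c A [new_compendium()] object.
#' @param array_ids Character vector of array ids to keep, in any order.
#' @return A `herg_compendium` restricted to those arrays.
#' @export
subset_arrays <- function(c, array_ids) {
  keep <- intersect(colnames(c$values), array_ids)
  if (length(keep) == 0) abort("selection removed every array (empty compendium)")
  new_compendium(c$values[, keep, drop = FALSE],
                 c$metadata[match(keep, c$metadata$array_id), ])
}

#' Response-profile set container
#'
#' Holds per-array or per-(drug, cell line) response profiles: log2 fold
#' changes versus batch mean. `info` carries one row per profile column.
#'
#' @param values Numeric matrix, probesets x profiles, with dimnames.
#' @param info Tibble with columns `profile_id`, `drug_id`, `cell_line` and
#'   optionally `batch_id`, `concentration`, `n_replicates_merged`.
#' @param masked Logical flag: differential-expression masking applied.
#' @return An object of class `herg_profiles`.
#' @export
new_profiles <- function(values, info, masked = FALSE) {
  info <- as_tibble(info)
  stopifnot(is.matrix(values), nrow(info) == ncol(values))
  if (!all(c("profile_id", "drug_id", "cell_line") %in% names(info))) {
    abort("profile info needs columns profile_id, drug_id, cell_line")
  }
  if (!setequal(info$profile_id, colnames(values))) {
    abort("profile ids disagree between matrix and info")
  }
  info <- info[match(colnames(values), info$profile_id), ]
  structure(list(values = values, info = info, masked = isTRUE(masked)),
            class = "herg_profiles")
}

#' @export
print.herg_profiles <- function(x, ...) {
  cat("<herg_profiles> ", nrow(x$values), " probesets x ", ncol(x$values),
      " profiles", if (x$masked) " (DE-masked)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.herg_profiles <- function(x) dim(x$values)
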