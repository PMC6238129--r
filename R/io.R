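egg_count_columns <- c("replicate_id", "strain", "treatment",
                       "patch_id", "substrate_id", "resource", "eggs")

#' Validate an egg-count dataset against a design registry
#'
#' Checks the long-format contract: required columns present; `eggs`
#' non-negative integers; every `treatment` resolves to a named design;
#' every (`patch_id`, `substrate_id`, `resource`) triple exists in that
#' design; no duplicated (`replicate_id`, `substrate_id`) pair within a
#' treatment. Validation errors name the offending row numbers. Replicates
#' whose total egg count is zero are legal; they are flagged in the
#' `zero_replicates` attribute of the returned data, never dropped.
#'
#' @param data A data frame in long format, one row per replicate x
#'   substrate, with columns `replicate_id`, `strain`, `treatment`,
#'   `patch_id`, `substrate_id`, `resource`, `eggs`.
#' @param designs Named list of [experiment_design()] objects (or a single
#'   design); names must match the `treatment` values in `data`.
#' @return The validated data as a tibble (row order preserved), with a
#'   `zero_replicates` attribute listing `treatment`/`replicate_id` pairs
#'   whose totals are zero.
#' @export
validate_egg_counts <- function(data, designs = standard_designs()) {
  designs <- check_design_registry(designs)
  missing_cols <- setdiff(egg_count_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Dataset is missing required column(s): %s.",
                  toString(missing_cols)))
  }
  data <- tibble::as_tibble(data)[egg_count_columns]
  row <- seq_len(nrow(data))

  bad_eggs <- which(is.na(data$eggs) | data$eggs < 0 |
                      data$eggs != as.integer(data$eggs))
  if (length(bad_eggs) > 0) {
    abort(sprintf("`eggs` must be non-negative integers; bad rows: %s.",
                  toString(head(bad_eggs, 10))))
  }
  data$eggs <- as.integer(data$eggs)

  unknown_trt <- which(!data$treatment %in% names(designs))
  if (length(unknown_trt) > 0) {
    abort(sprintf(
      "Unknown treatment(s) %s not in the design registry; rows: %s.",
      toString(unique(data$treatment[unknown_trt])),
      toString(head(unknown_trt, 10))
    ))
  }

  key <- function(p, s, r) paste(p, s, r, sep = "\r")
  for (trt in unique(data$treatment)) {
    idx <- which(data$treatment == trt)
    d <- designs[[trt]]
    ok <- key(data$patch_id[idx], data$substrate_id[idx], data$resource[idx]) %in%
      key(d$patch_id, d$substrate_id, d$resource)
    if (!all(ok)) {
      abort(sprintf(
        "Treatment '%s': substrate ids %s do not resolve against the design; rows: %s.",
        trt,
        toString(unique(data$substrate_id[idx[!ok]])),
        toString(head(idx[!ok], 10))
      ))
    }
    dup <- duplicated(paste(data$replicate_id[idx], data$substrate_id[idx], sep = "\r"))
    if (any(dup)) {
      abort(sprintf(
        "Treatment '%s': duplicated (replicate_id, substrate_id) pairs; rows: %s.",
        trt, toString(head(idx[dup], 10))
      ))
    }
  }

  zero <- data |>
    dplyr::group_by(.data$treatment, .data$replicate_id) |>
    dplyr::summarise(total = sum(.data$eggs), .groups = "drop") |>
    dplyr::filter(.data$total == 0) |>
    dplyr::select("treatment", "replicate_id")
  attr(data, "zero_replicates") <- zero
  data
}

#' Read an egg-count dataset from CSV
#'
#' Reads the package's long format (comma-separated, UTF-8, header
#' required: `replicate_id,strain,treatment,patch_id,substrate_id,resource,eggs`)
#' and validates it against a design registry via [validate_egg_counts()].
#' An empty file with a valid header yields an empty dataset with a warning.
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_egg_counts
#' @return A validated tibble; see [validate_egg_counts()].
#' @export
read_egg_counts <- function(path, designs = standard_designs()) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      replicate_id = readr::col_character(),
      strain = readr::col_character(),
      treatment = readr::col_character(),
      patch_id = readr::col_character(),
      substrate_id = readr::col_character(),
      resource = readr::col_character(),
      eggs = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(data) == 0) {
    warn(sprintf("'%s' contains a header but no rows; returning an empty dataset.", path))
  }
  validate_egg_counts(data, designs)
}

#' @rdname read_egg_counts
#' @param data A validated egg-count dataset.
#' @export
write_egg_counts <- function(data, path) {
  readr::write_csv(data[egg_count_columns], path, progress = FALSE)
  invisible(path)
}
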