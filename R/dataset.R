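dataset_schemas <- function() {
  list(
    spikes = c(cell_id = "integer", t = "double"),
    sniffs = c(sniff_id = "integer", t_onset = "double",
               t_inh_end = "double", t_end = "double", cell_id = "integer"),
    trials = c(cell_id = "integer", trial_id = "integer",
               odor = "character", concentration = "character",
               t_odor_on = "double"),
    light_trials = c(cell_id = "integer", t_sniff_on = "double",
                     light = "logical"),
    cells = c(cell_id = "integer", tagged = "logical")
  )
}

#' Write a dataset to delimited text
#'
#' Writes the event tables of a dataset (`spikes`, `sniffs`, `trials`,
#' and, when present, `light_trials` and `cells`) as UTF-8 CSV files with
#' a header row, plus a `meta.json` sidecar, into `dir`.
#'
#' @param dataset A dataset list as produced by
#'   [make_population_dataset()] or [load_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in intersect(names(dataset_schemas()), names(dataset))) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(dataset[[nm]]), p)
    paths <- c(paths, p)
  }
  if (!is.null(dataset$meta)) {
    p <- file.path(dir, "meta.json")
    jsonlite::write_json(dataset$meta, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Load a dataset from delimited text
#'
#' Reads the CSV tables written by [write_dataset()] (or prepared by
#' hand to the same schema) and validates them: required columns must be
#' present and numeric times finite, and every trial's `cell_id` must
#' exist in the sniff table (referential integrity).
#'
#' @param dir Directory containing `spikes.csv`, `sniffs.csv`,
#'   `trials.csv` and optionally `light_trials.csv`, `cells.csv`,
#'   `meta.json`.
#' @return A dataset list.
#' @export
load_dataset <- function(dir) {
  schemas <- dataset_schemas()
  required <- c("spikes", "sniffs", "trials")
  out <- list()
  for (nm in names(schemas)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) {
      if (nm %in% required) {
        rlang::abort(paste0("missing required table: ", basename(p)))
      }
      next
    }
    tab <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(names(schemas[[nm]]), names(tab))
    if (length(miss) > 0) {
      rlang::abort(sprintf("table %s is missing column(s): %s",
                           nm, paste(miss, collapse = ", ")))
    }
    num_cols <- names(schemas[[nm]])[schemas[[nm]] == "double"]
    for (cn in num_cols) {
      if (!is.numeric(tab[[cn]])) {
        rlang::abort(sprintf("column %s of %s is not numeric", cn, nm))
      }
      if (any(!is.finite(tab[[cn]]))) {
        rlang::abort(sprintf("column %s of %s has non-finite values", cn, nm))
      }
    }
    out[[nm]] <- tab
  }
  dangling <- setdiff(out$trials$cell_id, out$sniffs$cell_id)
  if (length(dangling) > 0) {
    rlang::abort(sprintf("trials reference cell_id(s) with no sniffs: %s",
                         paste(dangling, collapse = ", ")))
  }
  mp <- file.path(dir, "meta.json")
  if (file.exists(mp)) out$meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  out
}
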