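# Scan collections: the package's central table. One row per scan with
# subject/group/dataset/replicate metadata and a T x R timeseries matrix in a
# list-column, so the whole object pipes through dplyr verbs.

collection_meta_cols <- c("scan_id", "subject_id", "group", "dataset_id",
                          "replicate_index", "low_motion", "tr_seconds")

#' Validate a scan-collection tibble
#'
#' A scan collection is a tibble with columns `scan_id`, `subject_id`,
#' `group` (`"NC"` or `"PD"`), `dataset_id`, `replicate_index`, `low_motion`,
#' `tr_seconds` and a `timeseries` list-column of numeric `T x R` matrices
#' whose column names are the region ids (shared, in ascending label order,
#' across all scans). All downstream functions call this validator on entry.
#'
#' @param scans A candidate scan-collection data frame.
#' @return The collection as a tibble, invisibly checked.
#' @export
validate_collection <- function(scans) {
  scans <- as_tibble(scans)
  missing <- setdiff(c(collection_meta_cols, "timeseries"), names(scans))
  if (length(missing)) {
    abort(paste0("scan collection is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "fcrepro_schema_error")
  }
  bad_group <- setdiff(unique(scans$group), c("NC", "PD"))
  if (length(bad_group)) {
    abort(paste0("invalid group label(s): ",
                 paste(bad_group, collapse = ", "),
                 " (offending scans: ",
                 paste(scans$scan_id[scans$group %in% bad_group],
                       collapse = ", "), ")"),
          class = "fcrepro_validation_error")
  }
  key <- paste(scans$dataset_id, scans$scan_id)
  if (anyDuplicated(key)) {
    abort("duplicated (dataset_id, scan_id) keys in collection.",
          class = "fcrepro_validation_error")
  }
  regions <- lapply(scans$timeseries, colnames)
  if (length(regions) > 1 &&
      !all(vapply(regions[-1], identical, logical(1), regions[[1]]))) {
    abort("all scans in a collection must share identical region ids.",
          class = "fcrepro_schema_error")
  }
  ok_mat <- vapply(scans$timeseries,
                   function(m) is.matrix(m) && is.numeric(m) &&
                     all(is.finite(m)) && nrow(m) >= 2,
                   logical(1))
  if (!all(ok_mat)) {
    abort(paste0("non-finite or malformed timeseries for scan(s): ",
                 paste(scans$scan_id[!ok_mat], collapse = ", ")),
          class = "fcrepro_validation_error")
  }
  scans
}

#' Region ids of a collection
#' @param scans A scan collection (see [validate_collection()]).
#' @return Character vector of region ids.
#' @export
region_ids <- function(scans) {
  colnames(scans$timeseries[[1]])
}

#' Write / read a scan collection on disk
#'
#' The on-disk layout is plain text for diffability: one TSV per scan
#' (`<scan_id>.tsv`, `T` rows by `R` columns, header row of region ids) plus a
#' `metadata.tsv` with one row per scan. `write_scan_collection()` returns the
#' directory invisibly; `read_scan_collection()` validates on load and fails
#' listing the offending scan ids.
#'
#' @param scans A scan collection.
#' @param path Directory to write to / read from (created if needed).
#' @return `read_scan_collection()` returns the collection tibble.
#' @export
write_scan_collection <- function(scans, path) {
  scans <- validate_collection(scans)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- scans[, collection_meta_cols]
  readr::write_tsv(meta, file.path(path, "metadata.tsv"), progress = FALSE)
  for (i in seq_len(nrow(scans))) {
    m <- as.data.frame(scans$timeseries[[i]])
    names(m) <- colnames(scans$timeseries[[i]])
    readr::write_tsv(m, file.path(path, paste0(scans$scan_id[i], ".tsv")),
                     progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_scan_collection
#' @export
read_scan_collection <- function(path) {
  meta_path <- file.path(path, "metadata.tsv")
  if (!file.exists(meta_path)) {
    abort(paste0("no metadata.tsv under ", path),
          class = "fcrepro_io_error")
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(collection_meta_cols, names(meta))
  if (length(missing)) {
    abort(paste0("metadata.tsv is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "fcrepro_schema_error")
  }
  bad <- !meta$group %in% c("NC", "PD")
  if (any(bad)) {
    abort(paste0("invalid group label(s) in metadata for scan(s): ",
                 paste(meta$scan_id[bad], collapse = ", ")),
          class = "fcrepro_validation_error")
  }
  ts <- lapply(meta$scan_id, function(id) {
    f <- file.path(path, paste0(id, ".tsv"))
    if (!file.exists(f)) {
      abort(paste0("missing timeseries file for scan ", id),
            class = "fcrepro_io_error")
    }
    m <- as.matrix(readr::read_tsv(f, show_col_types = FALSE,
                                   progress = FALSE))
    storage.mode(m) <- "double"
    m
  })
  ncols <- vapply(ts, ncol, integer(1))
  if (length(unique(ncols)) > 1) {
    abort("scans in the collection have differing region counts.",
          class = "fcrepro_schema_error")
  }
  meta$replicate_index <- as.integer(meta$replicate_index)
  meta$low_motion <- as.logical(meta$low_motion)
  meta$timeseries <- ts
  validate_collection(meta)
}

#' Write simulation ground truth as JSON
#'
#' Persists the subtype assignment and the truly affected pairs of an
#' [simulate_cohort()] result next to the scan TSVs (per-scan target matrices
#' stay in memory only).
#'
#' @param sim An `fc_simulation`.
#' @param path Collection directory.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "fc_simulation"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(subtypes = sim$truth$subtypes, effects = sim$truth$effects),
    file.path(path, "ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
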