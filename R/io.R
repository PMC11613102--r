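# Plain-text readers/writers for the pipeline's tabular interchange
# formats: feature x sample TSV matrices, sample/cohort metadata TSV,
# fragment BED, rate-table CSV, plus a JSON sidecar recording seed and
# config hash for provenance.

#' Write a feature-by-sample table as TSV
#'
#' @param x Count/value tibble (first column `feature_id`) or matrix.
#' @param path Output path.
#' @param sidecar Optional list (e.g. `list(seed = 1, config = cfg)`)
#'   written as `<path>.json` with a config hash.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, sidecar = NULL) {
  tbl <- if (is.matrix(x)) as_feature_tibble(x) else x
  readr::write_tsv(tbl, path)
  if (!is.null(sidecar)) write_sidecar(path, sidecar)
  invisible(path)
}

#' Read a feature-by-sample TSV written by [write_matrix_tsv()]
#' @param path File path.
#' @return Tibble with `feature_id` plus sample columns.
#' @export
read_matrix_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write/read sample metadata or cohort tables as TSV
#' @param x Tibble.
#' @param path File path.
#' @param sidecar Optional provenance list.
#' @return `path` (writer) or tibble (reader).
#' @export
write_table_tsv <- function(x, path, sidecar = NULL) {
  readr::write_tsv(x, path)
  if (!is.null(sidecar)) write_sidecar(path, sidecar)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a reference incidence-rate table
#'
#' CSV with stratum columns (e.g. `age_group`, `gender`, `year_band`) and a
#' `rate` column in events per person-year.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_rate_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot_config("rate" %in% names(out) && all(out$rate >= 0),
                   "rate table needs a non-negative `rate` column")
  out
}

write_sidecar <- function(path, info) {
  side <- list(seed = info$seed %||% NA,
               config_hash = object_hash(info$config %||% info),
               written = "hmcprog")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
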