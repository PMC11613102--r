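valid_feature_classes <- c("gene_body", "promoter", "H3K4me1", "H3K27ac")

#' Validate an in-memory feature catalog
#'
#' A catalog maps feature ids to genomic intervals (BED convention: 0-based,
#' half-open) with a feature class — gene bodies, promoters, or
#' histone-mark (H3K4me1/H3K27ac) enhancer peaks. Overlapping features are
#' permitted: a fragment may be summarized into several classes.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `feature_id`,
#'   `feature_class`, and optionally `strand` (`+`, `-`, `.`) and
#'   `gene_symbol`.
#' @return A validated tibble.
#' @export
feature_catalog <- function(df) {
  need <- c("chrom", "start", "end", "feature_id", "feature_class")
  stopifnot_config(is.data.frame(df) && all(need %in% names(df)),
                   paste("catalog needs columns:", paste(need, collapse = ", ")))
  df <- as_tibble(df)
  if (!"strand" %in% names(df)) df$strand <- "."
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- ""
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    abort(paste0("catalog line ", bad[1], ": end <= start (",
                 df$feature_id[bad[1]], ")"), class = "hmcprog_parse_error")
  }
  bad_cls <- which(!df$feature_class %in% valid_feature_classes)
  if (length(bad_cls)) {
    abort(paste0("catalog line ", bad_cls[1], ": unknown feature class '",
                 df$feature_class[bad_cls[1]], "'"), class = "hmcprog_parse_error")
  }
  bad_strand <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad_strand)) {
    abort(paste0("catalog line ", bad_strand[1], ": invalid strand"),
          class = "hmcprog_parse_error")
  }
  dup <- df |>
    dplyr::count(.data$feature_class, .data$feature_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    line <- which(df$feature_id == dup$feature_id[1] &
                    df$feature_class == dup$feature_class[1])[2]
    abort(paste0("catalog line ", line, ": duplicate feature_id '",
                 dup$feature_id[1], "' within class ", dup$feature_class[1]),
          class = "hmcprog_parse_error")
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[c("chrom", "start", "end", "feature_id", "feature_class", "strand",
       "gene_symbol")]
}

#' Load a feature catalog from a BED-like file
#'
#' Expects a tab-separated file without header whose columns are
#' `chrom`, `start`, `end`, `feature_id`, `feature_class`, `strand`
#' and optionally `gene_symbol` (BED 0-based half-open coordinates).
#' Parse failures report the offending line.
#'
#' @param path File path.
#' @return A validated catalog tibble (see [feature_catalog()]).
#' @export
load_catalog <- function(path) {
  stopifnot_config(file.exists(path), paste("no such file:", path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("chrom", "start", "end", "feature_id",
                                         "feature_class", "strand",
                                         "gene_symbol")[1:min(7, max(utils::count.fields(path, sep = "\t")))],
                           fill = TRUE)
  feature_catalog(raw)
}

#' Write a catalog or fragment table as BED
#'
#' @param x Catalog or fragment tibble with `chrom`, `start`, `end` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "feature_id", "feature_class",
                      "strand", "sample_id"), names(x))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
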