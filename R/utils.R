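# Shared internal helpers.

# Round half away from zero (the convention used for the printed 2-decimal
# percentages in clinical tables; base round() is banker's rounding).
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "hmcprog_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage- or iteration-specific seed from a master seed, stably and
# within 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 1048573
  }
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483629 + 1)
}

stopifnot_config <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "hmcprog_config_error")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

check_proportions <- function(p, what) {
  stopifnot_config(
    is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) < 1e-8,
    paste0("`", what, "` must be non-negative proportions summing to 1.")
  )
}

# Convert a feature x sample count/value tibble (first column feature_id)
# to a numeric matrix with feature_id rownames. Matrices pass through.
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rownames(x) <- paste0("feat_", seq_len(nrow(x)))
    }
    return(x)
  }
  stopifnot_config(
    is.data.frame(x) && ncol(x) >= 2,
    "expected a matrix or a data frame with a feature id column followed by sample columns"
  )
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Inverse of as_feature_matrix(): matrix -> tibble with feature_id column.
as_feature_tibble <- function(m, id_col = "feature_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m) %||%
                                   paste0("feat_", seq_len(nrow(m)))), out)
  out
}

# Stable content hash of an R object (used for config/report provenance).
object_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
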