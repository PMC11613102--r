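#' Simulate enrichment-weighted fragment intervals on a toy genome
#'
#' Places sequencing-fragment intervals on the genome implied by a feature
#' catalog, with per-base sampling density proportional to a weight for each
#' feature class (uniform within a class). Used to exercise fragment
#' counting and metagene profiling against known enrichment patterns, e.g.
#' gene-body enrichment with promoter depletion around the TSS.
#'
#' @param catalog A feature catalog tibble (see [load_catalog()]).
#' @param weights Named non-negative weights per feature class; may include
#'   `background` for genomic positions not covered by the catalog.
#' @param n_fragments Number of fragments to draw (0 gives an empty table).
#' @param seed Integer seed.
#' @param fragment_length Fragment length in bp (must be <= 500, matching
#'   the concordant-pair length filter applied upstream of counting).
#' @param sample_id Sample label attached to every fragment.
#' @param chrom_sizes Optional tibble (`chrom`, `size`); defaults to the
#'   largest catalog end coordinate plus 10 kb per chromosome.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   `sample_id`, one row per fragment.
#' @export
simulate_fragments <- function(catalog, weights, n_fragments, seed = 1L,
                               fragment_length = 200L, sample_id = "sim",
                               chrom_sizes = NULL) {
  stopifnot_config(is.data.frame(catalog) && nrow(catalog) > 0,
                   "`catalog` must be a non-empty feature catalog.")
  stopifnot_config(is.numeric(weights) && !is.null(names(weights)) &&
                     all(weights >= 0), "`weights` must be named and non-negative.")
  stopifnot_config(any(weights > 0), "all class weights are zero; nothing to sample.")
  stopifnot_config(is_count(n_fragments), "`n_fragments` must be a count.")
  stopifnot_config(is_count(fragment_length) && fragment_length >= 1 &&
                     fragment_length <= 500,
                   "`fragment_length` must be in [1, 500].")

  if (is.null(chrom_sizes)) {
    chrom_sizes <- catalog |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(size = max(.data$end) + 10000L, .groups = "drop")
  }

  if (n_fragments == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  sample_id = character()))
  }

  # One interval pool per weighted class; "background" is the complement of
  # all cataloged intervals on the toy genome.
  pools <- list()
  for (cls in names(weights)) {
    if (weights[[cls]] == 0) next
    if (cls == "background") {
      bg <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
        ch <- chrom_sizes$chrom[i]
        cov <- catalog[catalog$chrom == ch, c("start", "end")]
        gaps <- interval_complement(cov$start, cov$end, chrom_sizes$size[i])
        if (nrow(gaps)) cbind(chrom = ch, gaps) else NULL
      })
      pool <- dplyr::bind_rows(bg)
    } else {
      pool <- catalog[catalog$feature_class == cls, c("chrom", "start", "end")]
    }
    stopifnot_config(nrow(pool) > 0,
                     paste0("no catalog intervals for weighted class '", cls, "'."))
    pools[[cls]] <- pool
  }

  with_seed(seed, {
    # Class chosen with probability proportional to weight x class length
    # (a per-base rate), midpoint uniform within the class's bases.
    lens <- vapply(pools, function(p) sum(p$end - p$start), numeric(1))
    w <- vapply(names(pools), function(cls) weights[[cls]], numeric(1)) * lens
    cls_draw <- sample(names(pools), n_fragments, replace = TRUE, prob = w)
    out <- lapply(names(pools), function(cls) {
      k <- sum(cls_draw == cls)
      if (k == 0) return(NULL)
      p <- pools[[cls]]
      seg_len <- p$end - p$start
      seg <- sample.int(nrow(p), k, replace = TRUE, prob = seg_len)
      mid <- p$start[seg] + floor(runif(k) * seg_len[seg])
      tibble(chrom = p$chrom[seg],
             start = as.integer(pmax(0, mid - floor(fragment_length / 2))),
             mid = as.integer(mid))
    })
    frags <- dplyr::bind_rows(out)
    # Anchor the midpoint exactly: [mid - floor(L/2), mid + ceiling(L/2)).
    frags$start <- frags$mid - floor(fragment_length / 2)
    shifted <- frags$start < 0
    frags$start[shifted] <- 0L
    frags$end <- frags$start + as.integer(fragment_length)
    frags$mid <- NULL
    frags$sample_id <- sample_id
    frags[order(frags$chrom, frags$start), ]
  })
}

# Complement of a set of [start, end) intervals within [0, size).
interval_complement <- function(starts, ends, size) {
  if (length(starts) == 0) return(tibble(start = 0L, end = as.integer(size)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  merged_s <- integer(0); merged_e <- integer(0)
  cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i]) else {
      merged_s <- c(merged_s, cs); merged_e <- c(merged_e, ce)
      cs <- starts[i]; ce <- ends[i]
    }
  }
  merged_s <- c(merged_s, cs); merged_e <- c(merged_e, ce)
  gs <- c(0L, merged_e); ge <- c(merged_s, as.integer(size))
  keep <- gs < ge
  tibble(start = as.integer(gs[keep]), end = as.integer(ge[keep]))
}
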