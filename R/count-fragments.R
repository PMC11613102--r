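# Fragment -> feature summarization and metagene profiling.
#
# All coordinates follow the BED convention (0-based, half-open). The
# default counting rule assigns a fragment to every feature whose interval
# contains the fragment midpoint; within any set of pairwise-disjoint
# features this gives each fragment at most one home, which prevents double
# counting across adjacent features. An any-overlap rule is available.

fragment_midpoint <- function(start, end) floor((start + end) / 2)

validate_fragments <- function(frags, max_length = 500L) {
  need <- c("chrom", "start", "end", "sample_id")
  stopifnot_config(is.data.frame(frags) && all(need %in% names(frags)),
                   paste("fragments need columns:", paste(need, collapse = ", ")))
  stopifnot_config(all(frags$end > frags$start) || nrow(frags) == 0,
                   "fragment intervals must satisfy start < end")
  too_long <- frags$end - frags$start > max_length
  if (any(too_long)) {
    warn(paste0(sum(too_long), " fragment(s) longer than ", max_length,
                " bp dropped (concordant-pair length filter)"))
    frags <- frags[!too_long, , drop = FALSE]
  }
  frags
}

#' Count fragments per catalog feature
#'
#' Summarizes per-sample fragment intervals over a feature catalog into a
#' feature-by-sample count matrix. Under the default `midpoint` rule the
#' entry for feature g and sample s is the number of sample-s fragments
#' whose midpoint lies inside g; under `overlap` any positive overlap
#' counts. Fragments longer than 500 bp are dropped with a warning, and
#' chromosomes present in the fragments but absent from the catalog
#' contribute nothing (warned).
#'
#' @param frags Fragment tibble: `chrom`, `start`, `end`, `sample_id`.
#' @param catalog A [feature_catalog()] tibble.
#' @param rule `"midpoint"` (default) or `"overlap"`.
#' @return A count tibble: `feature_id` plus one column per sample, ordered
#'   as in the catalog.
#' @export
count_fragments <- function(frags, catalog, rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  catalog <- feature_catalog(catalog)
  samples <- sort(unique(frags$sample_id))
  frags <- validate_fragments(frags)
  if (length(samples) == 0) samples <- "sample"
  missing_chrom <- setdiff(unique(frags$chrom), unique(catalog$chrom))
  if (length(missing_chrom)) {
    warn(paste0("fragments on chromosome(s) not in catalog counted as zero: ",
                paste(missing_chrom, collapse = ", ")))
  }
  # Catalog keys features by class + id so the same id may appear in
  # several classes; counts are reported per catalog row.
  key <- paste(catalog$feature_class, catalog$feature_id, sep = ":")
  counts <- matrix(0L, nrow = nrow(catalog), ncol = length(samples),
                   dimnames = list(key, samples))
  for (s in samples) {
    fs <- frags[frags$sample_id == s, , drop = FALSE]
    for (ch in unique(fs$chrom)) {
      fc <- fs[fs$chrom == ch, , drop = FALSE]
      rows <- which(catalog$chrom == ch)
      if (!length(rows) || !nrow(fc)) next
      if (rule == "midpoint") {
        mid <- sort(fragment_midpoint(fc$start, fc$end))
        # midpoint m in [start, end)  <=>  start <= m <= end - 1
        n_lt_end <- findInterval(catalog$end[rows] - 0.5, mid)
        n_lt_start <- findInterval(catalog$start[rows] - 0.5, mid)
        counts[rows, s] <- counts[rows, s] + (n_lt_end - n_lt_start)
      } else {
        fstart <- sort(fc$start)
        fend <- sort(fc$end)
        m <- nrow(fc)
        # overlap <=> frag_start < feat_end and frag_end > feat_start
        n_start_ge_end <- m - findInterval(catalog$end[rows] - 0.5, fstart)
        n_end_le_start <- findInterval(catalog$start[rows] + 0.5, fend)
        counts[rows, s] <- counts[rows, s] + (m - n_start_ge_end - n_end_le_start)
      }
    }
  }
  out <- as_feature_tibble(counts)
  out$feature_id <- catalog$feature_id
  out
}

#' Metagene profile over scaled gene bodies
#'
#' Computes the average fragment-midpoint density over gene bodies rescaled
#' to unit length (TSS to TES) with fixed-width flanks, the standard view
#' for checking that 5hmC-Seal signal is enriched across gene bodies and
#' depleted around the TSS. Minus-strand genes are orientation-flipped so
#' bin 1 is always the far upstream flank.
#'
#' @param frags Fragment tibble (`chrom`, `start`, `end`, `sample_id`).
#' @param gene_bodies Catalog rows of class `gene_body` (strand-aware).
#' @param n_body_bins Number of bins across the scaled body (default 100).
#' @param flank_bp Flank width in bp on each side (default 2000).
#' @param n_flank_bins Number of fixed-width bins per flank (default 20).
#' @return A tibble of class `hmc_metagene`: `bin` (1..2*n_flank_bins +
#'   n_body_bins), `region` (upstream/body/downstream), `density` (mean
#'   midpoints per kb per gene).
#' @export
metagene_profile <- function(frags, gene_bodies, n_body_bins = 100,
                             flank_bp = 2000, n_flank_bins = 20) {
  gene_bodies <- feature_catalog(gene_bodies)
  gene_bodies <- gene_bodies[gene_bodies$feature_class == "gene_body", ]
  stopifnot_config(nrow(gene_bodies) > 0, "no gene_body features in catalog")
  stopifnot_config(all(gene_bodies$end - gene_bodies$start >= n_body_bins),
                   "gene bodies must be at least n_body_bins bases long")
  frags <- validate_fragments(frags)
  total_bins <- 2L * n_flank_bins + n_body_bins
  flank_w <- flank_bp / n_flank_bins
  acc <- matrix(0, nrow(gene_bodies), total_bins)
  mids_by_chrom <- split(fragment_midpoint(frags$start, frags$end), frags$chrom)
  mids_by_chrom <- lapply(mids_by_chrom, sort)
  for (i in seq_len(nrow(gene_bodies))) {
    g <- gene_bodies[i, ]
    mids <- mids_by_chrom[[g$chrom]]
    if (is.null(mids)) next
    body_w <- (g$end - g$start) / n_body_bins
    edges <- c(g$start - flank_bp + flank_w * (0:n_flank_bins),
               g$start + body_w * (1:n_body_bins),
               g$end + flank_w * (1:n_flank_bins))
    cnt <- diff(findInterval(edges - 0.5, mids))
    widths <- diff(edges)
    dens <- cnt / widths * 1000
    if (g$strand == "-") dens <- rev(dens)
    acc[i, ] <- dens
  }
  region <- rep(c("upstream", "body", "downstream"),
                c(n_flank_bins, n_body_bins, n_flank_bins))
  out <- tibble(bin = seq_len(total_bins), region = region,
                density = colMeans(acc))
  class(out) <- c("hmc_metagene", class(out))
  attr(out, "layout") <- list(n_body_bins = n_body_bins, flank_bp = flank_bp,
                              n_flank_bins = n_flank_bins,
                              n_genes = nrow(gene_bodies))
  out
}
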