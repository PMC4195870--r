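#' Screening configuration
#'
#' Bundles every tunable threshold of the marker-discovery pipeline into a
#' validated list. Defaults mirror the published screening protocol: perfect
#' di- to penta-nucleotide repeats of at least five units, 300 bp flanks for
#' primer design, a 100 N contig spacer, and a tri-nucleotide-only candidate
#' filter with the top 20 candidates retained.
#'
#' @param unit_sizes Integer vector of repeat unit sizes to scan, a subset of
#'   2:5 (bp).
#' @param min_units Minimum number of complete repeat units for a locus to be
#'   reported (inclusive, default 5).
#' @param flank_len Flanking sequence length extracted on each side of a
#'   candidate repeat (bp, default 300).
#' @param spacer_len Number of `N` bases inserted between contigs when an
#'   assembly is concatenated into a single strand (default 100). Must be at
#'   least `max(unit_sizes) * min_units` so no reportable repeat can bridge a
#'   contig junction.
#' @param qual_min Minimum VCF QUAL for a supporting variant; records with
#'   missing QUAL fail any positive threshold (default 20).
#' @param fixed_low,fixed_high Pooled alternate-allele fraction at or below
#'   (`fixed_low`) / at or above (`fixed_high`) which a population is called
#'   fixed for the reference / alternate allele (defaults 0.05 and 0.95).
#' @param min_depth Minimum informative depth (ref + alt supporting reads) for
#'   a population call; below it the population is reported as `no_data`
#'   (default 8).
#' @param top_k Number of top-ranked candidates selected (default 20).
#' @param candidate_motif_sizes Unit sizes admitted by the candidate filter
#'   (default 3: tri-nucleotide repeats, which avoid the dinucleotide
#'   stutter-scoring problem).
#' @param rc_canonical If `TRUE`, motif classes are additionally folded across
#'   the reverse complement strand; by default only rotations are folded, so
#'   `ATC` and `GAT` remain distinct classes.
#'
#' @return A list of class `"str_config"`.
#' @examples
#' cfg <- str_config(min_units = 6)
#' cfg$flank_len
#' @export
str_config <- function(unit_sizes = 2:5,
                       min_units = 5L,
                       flank_len = 300L,
                       spacer_len = 100L,
                       qual_min = 20,
                       fixed_low = 0.05,
                       fixed_high = 0.95,
                       min_depth = 8L,
                       top_k = 20L,
                       candidate_motif_sizes = 3L,
                       rc_canonical = FALSE) {
  unit_sizes <- sort(unique(as.integer(unit_sizes)))
  if (length(unit_sizes) == 0L || !all(unit_sizes %in% 2:5)) {
    stop("`unit_sizes` must be a non-empty subset of 2:5", call. = FALSE)
  }
  min_units <- as.integer(min_units)
  if (is.na(min_units) || min_units < 2L) {
    stop("`min_units` must be an integer >= 2", call. = FALSE)
  }
  flank_len <- as.integer(flank_len)
  if (is.na(flank_len) || flank_len <= 0L) {
    stop("`flank_len` must be a positive integer", call. = FALSE)
  }
  spacer_len <- as.integer(spacer_len)
  if (is.na(spacer_len) || spacer_len < max(unit_sizes) * min_units) {
    stop(sprintf(
      "`spacer_len` must be >= max(unit_sizes) * min_units (= %d) so no STR can span a contig junction",
      max(unit_sizes) * min_units
    ), call. = FALSE)
  }
  if (!is.numeric(fixed_low) || !is.numeric(fixed_high) ||
      fixed_low < 0 || fixed_high > 1 || fixed_low >= fixed_high) {
    stop("need 0 <= fixed_low < fixed_high <= 1", call. = FALSE)
  }
  min_depth <- as.integer(min_depth)
  if (is.na(min_depth) || min_depth < 0L) {
    stop("`min_depth` must be a non-negative integer", call. = FALSE)
  }
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) {
    stop("`top_k` must be a positive integer", call. = FALSE)
  }
  candidate_motif_sizes <- sort(unique(as.integer(candidate_motif_sizes)))
  if (!all(candidate_motif_sizes %in% unit_sizes)) {
    stop("`candidate_motif_sizes` must be a subset of `unit_sizes`", call. = FALSE)
  }
  structure(
    list(
      unit_sizes = unit_sizes,
      min_units = min_units,
      flank_len = flank_len,
      spacer_len = spacer_len,
      qual_min = as.numeric(qual_min),
      fixed_low = as.numeric(fixed_low),
      fixed_high = as.numeric(fixed_high),
      min_depth = min_depth,
      top_k = top_k,
      candidate_motif_sizes = candidate_motif_sizes,
      rc_canonical = isTRUE(rc_canonical)
    ),
    class = "str_config"
  )
}

#' @export
print.str_config <- function(x, ...) {
  cat("STR screening configuration\n")
  cat("  unit sizes:            ", paste(x$unit_sizes, collapse = ","), "\n")
  cat("  min repeat units:      ", x$min_units, "\n")
  cat("  flank length (bp):     ", x$flank_len, "\n")
  cat("  contig spacer (N bp):  ", x$spacer_len, "\n")
  cat("  min variant QUAL:      ", x$qual_min, "\n")
  cat("  fixed thresholds:      ", x$fixed_low, "/", x$fixed_high, "\n")
  cat("  min informative depth: ", x$min_depth, "\n")
  cat("  candidate motif sizes: ", paste(x$candidate_motif_sizes, collapse = ","), "\n")
  cat("  top-k candidates:      ", x$top_k, "\n")
  invisible(x)
}
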