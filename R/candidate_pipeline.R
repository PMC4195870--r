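# Candidate filtering, ranking, and primer-ready output. The filter order
# defines the single reported exclusion reason: motif size first, then variant
# quality, then N-free complete flanks, then unit consistency.

EXCLUSION_REASONS <- c("motif-size", "low-qual", "flank-N", "non-unit-multiple")

#' Filter polymorphic repeat loci into primer-ready candidates
#'
#' Applies the validation filters in a fixed order; the first failing rule
#' becomes the locus's exclusion reason:
#' \enumerate{
#'   \item \emph{motif-size}: unit size must be in
#'     `config$candidate_motif_sizes` (default tri-nucleotide only, since
#'     di-nucleotide markers are hard to score due to PCR stutter);
#'   \item \emph{low-qual}: every supporting variant must have
#'     `QUAL >= qual_min`; a missing QUAL fails any positive threshold;
#'   \item \emph{flank-N}: both flanks must have exactly `flank_len` bases
#'     with no `N` call (an N within the flank window would compromise primer
#'     design; flanks reaching into a contig-junction spacer fail here
#'     automatically);
#'   \item \emph{non-unit-multiple}: every indel length must be a whole
#'     number of repeat units and no implied allele may have a negative
#'     repeat count (length changes that are not unit multiples indicate the
#'     variation is not simple repeat-count variation).
#' }
#'
#' @param pstrs Output of [population_status()] (or [assign_indels()]).
#' @param assembly The `assembly` the loci were found on.
#' @param config An [str_config()].
#' @return A list with `kept` (candidates, with `left_flank` and `right_flank`
#'   columns) and `excluded` (with an `exclusion_reason` column). The two
#'   partition the input.
#' @export
filter_candidates <- function(pstrs, assembly, config = str_config()) {
  n <- nrow(pstrs)
  reason <- rep(NA_character_, n)
  left <- character(n)
  right <- character(n)
  qmin <- config$qual_min
  for (r in seq_len(n)) {
    fl <- extract_flanks(assembly, pstrs$contig[r], pstrs$start[r], pstrs$end[r],
                         config$flank_len)
    left[r] <- fl$left
    right[r] <- fl$right
    if (!pstrs$unit_size[r] %in% config$candidate_motif_sizes) {
      reason[r] <- "motif-size"
    } else if ((pstrs$has_missing_qual[r] && qmin > 0) ||
               (!is.na(pstrs$min_qual[r]) && pstrs$min_qual[r] < qmin)) {
      reason[r] <- "low-qual"
    } else if (!fl$complete || grepl("N", fl$left, fixed = TRUE) ||
               grepl("N", fl$right, fixed = TRUE)) {
      reason[r] <- "flank-N"
    } else if (!pstrs$unit_consistent[r]) {
      reason[r] <- "non-unit-multiple"
    }
  }
  pstrs$left_flank <- left
  pstrs$right_flank <- right
  kept <- pstrs[is.na(reason), , drop = FALSE]
  excluded <- pstrs[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]
  rownames(kept) <- NULL
  rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Rank candidates and select the top k
#'
#' Candidates are ordered by the largest implied repeat count of any allele
#' (descending) — longer repeats are the most informative markers — with ties
#' broken by reference repeat count (descending), then contig name and start
#' (ascending). The order is total, so selection does not depend on the input
#' order.
#'
#' @param kept Candidate table from [filter_candidates()].
#' @param top_k Number of candidates to return (default 20).
#' @return The first `top_k` rows in rank order.
#' @export
rank_and_select <- function(kept, top_k = 20L) {
  if (nrow(kept) == 0L) return(kept)
  ord <- order(-kept$max_allele_units, -kept$units, kept$contig, kept$start,
               method = "radix")
  out <- kept[utils::head(ord, top_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected maximum PCR fragment length of a marker
#'
#' Alleles of an STR marker differ in amplicon size by the unit size times the
#' repeat-count difference: a marker whose shortest allele amplifies at
#' `min_len_bp` with `min_units` repeats reaches
#' `min_len_bp + unit_size * (max_units - min_units)` at `max_units` repeats.
#' Useful to sanity-check observed fragment ranges against the allele range
#' implied by the repeat counts.
#'
#' @param min_len_bp Fragment length of the shortest allele (bp).
#' @param unit_size Repeat unit size (bp).
#' @param min_units,max_units Smallest and largest repeat count.
#' @return Maximum fragment length in bp.
#' @examples
#' expected_fragment_span(366, 3, 14, 18) # 378
#' @export
expected_fragment_span <- function(min_len_bp, unit_size, min_units, max_units) {
  stopifnot(max_units >= min_units, min_units >= 0)
  min_len_bp + unit_size * (max_units - min_units)
}

candidate_title <- function(cand) {
  sprintf(
    ">%s|%d-%d|%sx%d|alleles=%d-%d|pops=%s",
    cand$contig, cand$start + 1L, cand$end, cand$motif, cand$units,
    cand$min_allele_units, cand$max_allele_units,
    cand$pop_summary %||na% "NA"
  )
}

write_candidate_records <- function(candidates, path, width = 70L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (r in seq_len(nrow(candidates))) {
    cand <- candidates[r, , drop = FALSE]
    writeLines(candidate_title(cand), con)
    seq <- paste0(cand$left_flank, strrep(cand$motif, cand$units), cand$right_flank)
    writeLines(wrap_sequence(seq, width), con)
  }
  invisible(path)
}

#' Write primer-ready candidate FASTA
#'
#' One record per candidate. The title encodes the locus location (1-based
#' inclusive), motif and reference repeat count, the implied allele range, and
#' the per-population status; the sequence is
#' `left_flank + motif x units + right_flank`, so the repeat starts at offset
#' `flank_len` in every record.
#'
#' @param candidates Ranked candidates from [rank_and_select()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_candidate_fasta <- function(candidates, path) {
  write_candidate_records(candidates, path)
}

#' Write the fixed-in-some-population candidate FASTA
#'
#' The subset of candidates at which one population is fixed while another is
#' polymorphic or fixed for a different allele. Written even when empty.
#'
#' @inheritParams write_candidate_fasta
#' @export
write_fixed_fasta <- function(candidates, path) {
  fixed <- candidates[isTRUE_vec(candidates$fixed_in_some), , drop = FALSE]
  write_candidate_records(fixed, path)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write the full screening report as TSV
#'
#' One row per repeat locus with at least one assigned indel: location, motif,
#' allele range, per-population status, and whether the locus was kept or the
#' exclusion reason.
#'
#' @param kept,excluded The two halves from [filter_candidates()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(kept, excluded, path) {
  fmt <- function(df, verdict, reason) {
    if (nrow(df) == 0L) return(NULL)
    data.frame(
      contig = df$contig, start = df$start + 1L, end = df$end,
      motif = df$motif, unit_size = df$unit_size, units = df$units,
      allele_units = vapply(df$allele_units, paste, character(1), collapse = ","),
      n_variants = df$n_variants,
      min_qual = df$min_qual,
      pop_status = if (is.null(df$pop_summary)) NA_character_ else df$pop_summary,
      fixed_in_some = if (is.null(df$fixed_in_some)) NA else df$fixed_in_some,
      verdict = verdict,
      reason = reason,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    fmt(kept, "candidate", ""),
    fmt(excluded, "excluded", excluded$exclusion_reason)
  )
  if (is.null(out)) {
    out <- data.frame(contig = character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full marker-discovery pipeline
#'
#' Reads an assembly and a VCF of pooled-population variant calls, scans for
#' perfect repeats, keeps the indel records, left-normalizes them, assigns
#' them to repeat loci, classifies per-population status, applies the
#' candidate filters, ranks, selects the top k, and optionally writes the
#' candidate FASTA, the fixed-list FASTA, and the TSV report.
#'
#' @param fasta Path to the assembly (FASTA or tab dialect, optionally `.gz`),
#'   or an `assembly` object.
#' @param vcf Path to the VCF (optionally `.gz`), or a `vcf_set`.
#' @param config An [str_config()].
#' @param dialect Assembly dialect passed to [read_assembly()].
#' @param pops Populations to classify (default: all VCF samples).
#' @param concat If `TRUE`, concatenate the contigs with an N spacer before
#'   scanning and translate loci back to contig coordinates (the whole-genome
#'   single-strand mode; results are identical by construction).
#' @param out,fixed_out,report Optional output paths.
#' @return A list with `loci`, `pstrs`, `kept`, `excluded`, `candidates`
#'   (the ranked top k) and `summary` (stage counts).
#' @export
discover_markers <- function(fasta, vcf, config = str_config(),
                             dialect = "auto", pops = NULL, concat = FALSE,
                             out = NULL, fixed_out = NULL, report = NULL) {
  assembly <- if (inherits(fasta, "assembly")) fasta else read_assembly(fasta, dialect)
  vcfset <- if (inherits(vcf, "vcf_set")) vcf else parse_vcf(vcf)

  if (concat && length(assembly$records) > 1L) {
    joined <- concat_with_spacer(assembly, config$spacer_len,
                                 min_span = max(config$unit_sizes) * config$min_units)
    loci <- translate_loci(find_strs(joined, config), joined)
  } else {
    loci <- find_strs(assembly, config)
  }

  indels <- select_indels(vcfset)
  indels <- normalize_indels(indels, assembly)
  pstrs <- assign_indels(loci, indels, config)
  pstrs <- population_status(pstrs, vcfset, config, pops)
  flt <- filter_candidates(pstrs, assembly, config)
  ranked <- rank_and_select(flt$kept, top_k = max(1L, nrow(flt$kept)))
  candidates <- utils::head(ranked, config$top_k)

  if (!is.null(out)) write_candidate_fasta(candidates, out)
  # the fixed list covers every kept candidate, not only the top k
  if (!is.null(fixed_out)) write_fixed_fasta(ranked, fixed_out)
  if (!is.null(report)) write_report(flt$kept, flt$excluded, report)

  excl_by_reason <- table(factor(flt$excluded$exclusion_reason,
                                 levels = EXCLUSION_REASONS))
  summary <- list(
    n_contigs = length(assembly$records),
    n_loci = nrow(loci),
    loci_by_unit_size = as.list(table(factor(loci$unit_size, levels = config$unit_sizes))),
    n_variants = nrow(vcfset$variants),
    n_indels = nrow(indels$variants),
    n_assigned_loci = nrow(pstrs),
    n_unassigned_indels = attr(pstrs, "n_unassigned"),
    n_kept = nrow(flt$kept),
    excluded_by_reason = as.list(excl_by_reason),
    n_candidates = nrow(candidates),
    n_fixed = sum(isTRUE_vec(ranked$fixed_in_some))
  )
  list(
    loci = loci, pstrs = pstrs, kept = flt$kept, excluded = flt$excluded,
    candidates = candidates, summary = summary
  )
}
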