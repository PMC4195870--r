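# Core of the method: intersect left-normalized indels with repeat loci,
# translate indel lengths into per-allele repeat counts, and classify each
# locus per population as polymorphic or fixed from pooled allele depths.

#' Assign indels to repeat loci
#'
#' An indel is assigned to a locus when its normalized edit interval
#' (anchor base plus any deleted bases, 0-based half-open) lies within
#' `[start - unit_size, end)` of the locus; the left extension accounts for
#' left-normalized indels anchoring one base before the event. When several
#' loci qualify, the locus whose unit size divides the indel length wins;
#' remaining ties go to the longest locus, then the smallest start.
#'
#' @param loci Locus table from [find_strs()].
#' @param vcf A `vcf_set` of normalized indels (see [normalize_indels()]).
#' @param config An [str_config()].
#' @return A data frame with one row per locus that received at least one
#'   indel: the locus columns plus `n_variants`, `var_ids` (list), `deltas`
#'   (list), `allele_units` (list of implied repeat counts, reference
#'   included), `min_allele_units`, `max_allele_units`, `unit_consistent`
#'   (all deltas are unit multiples and no implied count is negative),
#'   `min_qual` and `has_missing_qual`. Loci with no assigned indel are not
#'   reported. Indels assignable to no locus are counted in the
#'   `"n_unassigned"` attribute.
#' @export
assign_indels <- function(loci, vcf, config = str_config()) {
  v <- vcf$variants
  v <- v[v$kind == "INDEL", , drop = FALSE]
  assigned_locus <- rep(NA_integer_, nrow(v))
  for (i in seq_len(nrow(v))) {
    edit_start <- v$pos[i] - 1L                  # 0-based anchor
    edit_end <- edit_start + nchar(v$ref[i])
    cand <- which(
      loci$contig == v$contig[i] &
        edit_start >= loci$start - loci$unit_size &
        edit_end <= loci$end
    )
    if (length(cand) == 0L) next
    if (length(cand) > 1L) {
      divides <- abs(v$length_delta[i]) %% loci$unit_size[cand] == 0L
      if (any(divides)) cand <- cand[divides]
      len <- loci$end[cand] - loci$start[cand]
      cand <- cand[order(-len, loci$start[cand], method = "radix")]
    }
    assigned_locus[i] <- cand[1L]
  }
  n_unassigned <- sum(is.na(assigned_locus))

  hit <- sort(unique(assigned_locus[!is.na(assigned_locus)]))
  rows <- lapply(hit, function(li) {
    vi <- which(assigned_locus == li)
    deltas <- v$length_delta[vi]
    k <- loci$unit_size[li]
    mult <- deltas %% k == 0L
    implied <- loci$units[li] + deltas[mult] %/% k
    allele_units <- sort(unique(c(loci$units[li], implied)))
    quals <- v$qual[vi]
    cbind(
      loci[li, , drop = FALSE],
      data.frame(
        locus_id = li,
        n_variants = length(vi),
        min_allele_units = min(allele_units),
        max_allele_units = max(allele_units),
        unit_consistent = all(mult) && min(allele_units) >= 0L,
        min_qual = if (all(is.na(quals))) NA_real_ else min(quals, na.rm = TRUE),
        has_missing_qual = anyNA(quals),
        stringsAsFactors = FALSE
      )
    )
  })
  out <- do.call(rbind, c(list(empty_pstrs()), rows))
  rownames(out) <- NULL
  out$var_ids <- lapply(hit, function(li) v$var_id[which(assigned_locus == li)])
  out$deltas <- lapply(hit, function(li) v$length_delta[which(assigned_locus == li)])
  out$allele_units <- lapply(seq_len(nrow(out)), function(r) {
    k <- out$unit_size[r]
    d <- out$deltas[[r]]
    sort(unique(c(out$units[r], out$units[r] + d[d %% k == 0L] %/% k)))
  })
  attr(out, "n_unassigned") <- n_unassigned
  out
}

empty_pstrs <- function() {
  cbind(
    empty_loci(),
    data.frame(
      locus_id = integer(0), n_variants = integer(0),
      min_allele_units = integer(0), max_allele_units = integer(0),
      unit_consistent = logical(0), min_qual = numeric(0),
      has_missing_qual = logical(0), stringsAsFactors = FALSE
    )
  )
}

#' Classify per-population polymorphic/fixed status
#'
#' For every locus and population pool, the pooled alternate-allele fraction
#' `f = alt / (ref + alt)` is computed per assigned variant; variants with
#' informative depth (`ref + alt`) below `min_depth` are ignored. The status
#' uses the maximum fraction over informative variants (the most permissive
#' evidence of polymorphism): `fixed_ref` when `f <= fixed_low`, `fixed_alt`
#' when `f >= fixed_high`, otherwise `polymorphic`; `no_data` when no variant
#' is informative. A locus is flagged `fixed_in_some` when at least one
#' population is fixed while another is polymorphic or fixed for a different
#' allele — the loci most useful for distinguishing populations.
#'
#' @param pstrs Output of [assign_indels()].
#' @param vcf The `vcf_set` the indels came from (for allele support).
#' @param config An [str_config()].
#' @param pops Populations (sample names) to classify; defaults to all samples
#'   in the VCF. Unknown names are an error.
#' @return `pstrs` with one `status_<pop>` column per population, a
#'   `pop_summary` string, and `fixed_in_some`.
#' @export
population_status <- function(pstrs, vcf, config = str_config(), pops = NULL) {
  if (is.null(pops)) pops <- vcf$samples
  unknown <- setdiff(pops, vcf$samples)
  if (length(unknown) > 0L) {
    stop_usage(sprintf(
      "population(s) not present in the VCF: %s (samples are: %s)",
      paste(unknown, collapse = ", "), paste(vcf$samples, collapse = ", ")
    ))
  }
  sup <- vcf$support
  status <- matrix(NA_character_, nrow = nrow(pstrs), ncol = length(pops),
                   dimnames = list(NULL, pops))
  for (r in seq_len(nrow(pstrs))) {
    vids <- pstrs$var_ids[[r]]
    for (p in pops) {
      rows <- sup[sup$var_id %in% vids & sup$sample == p, , drop = FALSE]
      informative <- rows$ref_count + rows$alt_count >= config$min_depth
      if (!any(informative)) {
        status[r, p] <- "no_data"
        next
      }
      f <- max(rows$alt_count[informative] /
                 (rows$ref_count[informative] + rows$alt_count[informative]))
      status[r, p] <- if (f <= config$fixed_low) "fixed_ref"
        else if (f >= config$fixed_high) "fixed_alt"
        else "polymorphic"
    }
  }
  for (p in pops) pstrs[[paste0("status_", p)]] <- status[, p]
  pstrs$fixed_in_some <- apply(status, 1L, function(st) {
    st <- st[st != "no_data"]
    fixed <- st[st %in% c("fixed_ref", "fixed_alt")]
    length(fixed) > 0L &&
      (any(st == "polymorphic") || length(unique(fixed)) > 1L)
  })
  pstrs$pop_summary <- apply(status, 1L, function(st) {
    paste(paste0(pops, ":", st), collapse = ",")
  })
  pstrs
}
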