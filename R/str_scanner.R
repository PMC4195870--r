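# Perfect tandem repeat detection.
#
# A locus is one maximal periodic region: the interval cannot be extended by a
# single base on either side while keeping the period, the repeat unit (the
# first unit_size bases, i.e. the phase at the region start) is primitive, N
# breaks any run, and the reported interval covers only complete units
# (a trailing partial unit is dropped from the coordinates but still blocks
# rightward extension). Each physical run is therefore reported exactly once,
# at its primitive unit size.

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not itself a whole number of copies of a
#' shorter string (`ATAT` is two copies of `AT`, hence not primitive).
#'
#' @param motif Character vector of repeat units.
#' @return Logical vector.
#' @export
is_primitive <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k <= 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && strrep(substr(m, 1L, d), k %/% d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) {
    paste0(substr(m, i, k), substr(m, 1L, i - 1L))
  }, character(1))
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    x,
    function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE
  ))
}

#' Canonical representative of a motif class
#'
#' Returns the lexicographically minimal rotation of a primitive motif, so that
#' e.g. `TCA`, `CAT` and `ATC` all aggregate into the `ATC` class in summary
#' tables. Strand folding (also considering the reverse complement's rotations)
#' is off by default: the displayed motif keeps the phase and strand observed
#' at the reference locus.
#'
#' @param motif Character vector of primitive motifs over A/C/G/T.
#' @param rc If `TRUE`, fold motif classes across strands as well.
#' @return Character vector of canonical motifs.
#' @examples
#' canonical_motif("TCA") # "ATC"
#' @export
canonical_motif <- function(motif, rc = FALSE) {
  bad <- !is_primitive(motif)
  if (any(bad)) {
    stop(sprintf("motif '%s' is not primitive", motif[bad][1L]), call. = FALSE)
  }
  vapply(motif, function(m) {
    cand <- rotations(m)
    if (rc) cand <- c(cand, rotations(revcomp(m)))
    min(cand)
  }, character(1), USE.NAMES = FALSE)
}

empty_loci <- function() {
  data.frame(
    contig = character(0), start = integer(0), end = integer(0),
    motif = character(0), canonical_motif = character(0),
    unit_size = integer(0), units = integer(0),
    stringsAsFactors = FALSE
  )
}

order_loci <- function(loci) {
  order(loci$contig, loci$start, loci$unit_size, method = "radix")
}

#' Find all perfect tandem repeats in an assembly
#'
#' Scans every contig for maximal perfect tandem repeats of the configured
#' unit sizes with at least `min_units` complete copies. Runs containing `N`
#' are never reported (`N` splits a run into independent sides). Overlapping
#' loci of different unit sizes are all reported; a run whose unit is not
#' primitive is reported only at its primitive unit size.
#'
#' @param x An `assembly` object or a named character vector of sequences.
#' @param config An [str_config()]; `unit_sizes` and `min_units` are used.
#' @return A data frame with one row per locus: `contig`, `start`, `end`
#'   (0-based half-open), `motif` (unit as phased at the run start),
#'   `canonical_motif`, `unit_size`, `units`; sorted by contig then start.
#' @examples
#' find_strs(c(c1 = strrep("ATC", 6)), str_config())
#' @export
find_strs <- function(x, config = str_config()) {
  seqs <- if (inherits(x, "assembly")) x$records else x
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named", call. = FALSE)
  }
  res <- lapply(names(seqs), function(nm) {
    scan_sequence(seqs[[nm]], nm, config$unit_sizes, config$min_units, config$rc_canonical)
  })
  out <- do.call(rbind, c(list(empty_loci()), res))
  out <- out[order_loci(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_sequence <- function(seq, contig, unit_sizes, min_units, rc_canonical = FALSE) {
  n <- nchar(seq)
  r <- charToRaw(seq)
  base_ok <- r == as.raw(65L) | r == as.raw(67L) | r == as.raw(71L) | r == as.raw(84L)
  rows <- list()
  for (k in unit_sizes) {
    if (n < k * min_units) next
    # match[i] <- s[i] == s[i+k], both unambiguous bases
    m <- r[seq_len(n - k)] == r[(k + 1L):n] &
      base_ok[seq_len(n - k)] & base_ok[(k + 1L):n]
    rl <- rle(m)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & rl$lengths >= (min_units - 1L) * k)
    for (h in hit) {
      i <- starts[h]                       # 1-based region start
      region_len <- rl$lengths[h] + k
      units <- region_len %/% k
      if (units < min_units) next
      motif <- substr(seq, i, i + k - 1L)
      if (!is_primitive(motif)) next       # reported at its primitive unit size
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig,
        start = i - 1L,
        end = i - 1L + units * k,
        motif = motif,
        canonical_motif = canonical_motif(motif, rc = rc_canonical),
        unit_size = as.integer(k),
        units = as.integer(units),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_loci())
  do.call(rbind, rows)
}

#' Tabulate repeat counts by motif size
#'
#' Builds the standard discovery summary: rows are repeat counts (5 up to
#' `max_row`, then a pooled `>max_row` class), columns are motif sizes (di,
#' tri, tetra, penta), cells are locus counts, followed by a column-sum row
#' and a percent row giving each motif size's share of all loci.
#'
#' @param loci Locus table from [find_strs()].
#' @param min_row,max_row Smallest and largest repeat count given its own row.
#' @return A data frame with a `repeats` column and one column per motif size.
#' @export
summarize_counts <- function(loci, min_row = 5L, max_row = 20L) {
  sizes <- c(di = 2L, tri = 3L, tetra = 4L, penta = 5L)
  counts <- seq.int(min_row, max_row)
  labels <- c(as.character(counts), paste0(max_row + 1L, "+"))
  tab <- matrix(0, nrow = length(labels), ncol = length(sizes),
                dimnames = list(labels, names(sizes)))
  if (nrow(loci) > 0L) {
    row_of <- ifelse(loci$units > max_row, length(labels),
                     loci$units - min_row + 1L)
    ok <- loci$units >= min_row
    for (j in seq_along(sizes)) {
      sel <- ok & loci$unit_size == sizes[j]
      if (any(sel)) {
        t_j <- table(factor(row_of[sel], levels = seq_along(labels)))
        tab[, j] <- as.integer(t_j)
      }
    }
  }
  sums <- colSums(tab)
  pct <- if (sum(sums) > 0) round(100 * sums / sum(sums), 1) else rep(0, length(sizes))
  out <- data.frame(
    repeats = c(labels, "SUM", "percent"),
    rbind(tab, SUM = sums, percent = pct),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Write loci as a BED track
#'
#' 0-based half-open intervals with name `motif x units` and the repeat count
#' as score.
#'
#' @param loci Locus table from [find_strs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  lines <- sprintf("%s\t%d\t%d\t%sx%d\t%d", loci$contig, loci$start, loci$end,
                   loci$motif, loci$units, loci$units)
  writeLines(lines, path)
  invisible(path)
}
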