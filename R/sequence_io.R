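ASSEMBLY_ALPHABET <- "ACGTN"

new_assembly <- function(records, dialect = "fasta", coord_map = NULL) {
  structure(
    list(records = records, dialect = dialect, coord_map = coord_map),
    class = "assembly"
  )
}

#' @export
print.assembly <- function(x, ...) {
  n <- length(x$records)
  cat(sprintf(
    "Assembly: %d contig%s, %s bp total (%s dialect)%s\n",
    n, if (n == 1L) "" else "s",
    format(sum(nchar(x$records)), big.mark = ","),
    x$dialect,
    if (is.null(x$coord_map)) "" else ", concatenated with coordinate map"
  ))
  show <- utils::head(x$records, 3L)
  for (i in seq_along(show)) {
    cat(sprintf("  %s (%d bp)\n", names(show)[i], nchar(show[[i]])))
  }
  if (n > 3L) cat(sprintf("  ... and %d more\n", n - 3L))
  invisible(x)
}

validate_sequences <- function(seqs, where = "sequence") {
  bad <- grepl(sprintf("[^%s]", ASSEMBLY_ALPHABET), seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr(sprintf("[^%s]", ASSEMBLY_ALPHABET), seqs[i]))
    stop(sprintf(
      "illegal character '%s' in %s '%s' (alphabet is A/C/G/T/N; IUPAC ambiguity codes are not accepted)",
      ch, where, names(seqs)[i] %||% i
    ), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    i <- which(!nzchar(seqs))[1L]
    stop(sprintf("record '%s' has an empty sequence", names(seqs)[i] %||% i), call. = FALSE)
  }
  invisible(seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_lines_any <- function(path) {
  if (!file.exists(path)) {
    stop_data(sprintf("input file not found: %s", path))
  }
  con <- gzfile(path, open = "rt")  # transparently reads plain or gzip text
  on.exit(close(con))
  sub("\r$", "", readLines(con, warn = FALSE))
}

#' Read an assembly in FASTA or tab-delimited dialect
#'
#' Reads a (draft) assembly from either standard FASTA (a `>`-prefixed title
#' line followed by one or more sequence lines, any line wrap) or the
#' tab-delimited dialect in which each record is a single line holding the
#' sequence name and the sequence separated by one tab. Files may be plain
#' text or gzip-compressed. Sequences are uppercased; any residue outside
#' A/C/G/T/N is a hard error, as are duplicate record names.
#'
#' @param path Path to the assembly file (optionally `.gz`).
#' @param dialect `"fasta"`, `"tab"`, or `"auto"` (default), which sniffs the
#'   first non-empty character: `>` means FASTA, anything else the tab dialect.
#' @return An `assembly` object: a named character vector of uppercase contig
#'   sequences plus the dialect it was read from.
#' @seealso [write_assembly()], [concat_with_spacer()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTACGT"), fa)
#' read_assembly(fa)
#' @export
read_assembly <- function(path, dialect = c("auto", "fasta", "tab")) {
  dialect <- match.arg(dialect)
  lines <- read_lines_any(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    stop_data(sprintf("assembly file '%s' is empty", path))
  }
  if (dialect == "auto") {
    dialect <- if (startsWith(trimws(lines[nonempty[1L]]), ">")) "fasta" else "tab"
  }
  records <- if (dialect == "fasta") {
    parse_fasta_lines(lines, path)
  } else {
    parse_tab_lines(lines, path)
  }
  records <- toupper(records)
  if (anyDuplicated(names(records))) {
    dup <- names(records)[duplicated(names(records))][1L]
    stop_data(sprintf("duplicate record name '%s' in '%s'", dup, path))
  }
  validate_sequences(records)
  new_assembly(records, dialect = dialect)
}

parse_fasta_lines <- function(lines, path) {
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_data(sprintf("no records in '%s'", path))
  is_title <- startsWith(lines, ">")
  if (!is_title[1L]) {
    stop_data(sprintf(
      "malformed FASTA in '%s': line %d does not start with '>' and precedes any record title",
      path, lineno[1L]
    ))
  }
  rec_id <- cumsum(is_title)
  titles <- trimws(sub("^>", "", lines[is_title]))
  if (any(!nzchar(titles))) {
    bad <- lineno[is_title][which(!nzchar(titles))[1L]]
    stop_data(sprintf("malformed FASTA in '%s': empty record name at line %d", path, bad))
  }
  seqs <- vapply(
    split(lines[!is_title], rec_id[!is_title]),
    function(x) paste(gsub("[[:space:]]", "", x), collapse = ""),
    character(1)
  )
  out <- character(length(titles))
  names(out) <- titles
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    stop_data(sprintf(
      "record '%s' in '%s' has no sequence lines",
      titles[which(!nzchar(out))[1L]], path
    ))
  }
  out
}

parse_tab_lines <- function(lines, path) {
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ntab <- lengths(parts) - 1L
  bad <- which(ntab != 1L)
  if (length(bad) > 0L) {
    stop_data(sprintf(
      "malformed tab-dialect line %d in '%s': expected exactly one tab, found %d",
      keep[bad[1L]], path, ntab[bad[1L]]
    ))
  }
  out <- vapply(parts, function(p) trimws(p[2L]), character(1))
  names(out) <- vapply(parts, function(p) trimws(p[1L]), character(1))
  if (any(!nzchar(names(out)))) {
    stop_data(sprintf(
      "malformed tab-dialect line %d in '%s': empty record name",
      keep[which(!nzchar(names(out)))[1L]], path
    ))
  }
  out
}

#' Write an assembly
#'
#' @param assembly An `assembly` object or named character vector of sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param dialect `"fasta"` (default) or `"tab"`.
#' @param width Line width for FASTA sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path, dialect = c("fasta", "tab"), width = 70L) {
  dialect <- match.arg(dialect)
  records <- if (inherits(assembly, "assembly")) assembly$records else assembly
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (dialect == "tab") {
    writeLines(paste(names(records), records, sep = "\t"), con)
  } else {
    for (i in seq_along(records)) {
      writeLines(paste0(">", names(records)[i]), con)
      writeLines(wrap_sequence(records[[i]], width), con)
    }
  }
  invisible(path)
}

wrap_sequence <- function(seq, width = 70L) {
  n <- nchar(seq)
  if (n <= width) return(seq)
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

#' Concatenate contigs into one strand with an N spacer
#'
#' Joins all contigs of an assembly, in order, into a single continuous
#' sequence with runs of `spacer_len` `N` bases between consecutive contigs,
#' and records a coordinate map from the concatenated strand back to
#' per-contig coordinates. The spacer must be long enough that no reportable
#' repeat can bridge a junction (`N` additionally breaks any repeat run), so
#' scanning the concatenated strand is equivalent to scanning each contig.
#'
#' @param assembly An `assembly` object.
#' @param spacer_len Spacer length in bp (default 100).
#' @param min_span Lower bound enforced on `spacer_len`; defaults to the
#'   longest reportable repeat span under the default configuration
#'   (`max(unit_sizes) * min_units` = 25 bp).
#' @param name Name given to the single concatenated record.
#' @return An `assembly` with one record and a populated `coord_map`
#'   (data frame with columns `contig`, `offset` 0-based, `length`).
#' @seealso [map_concat_position()], [translate_loci()]
#' @export
concat_with_spacer <- function(assembly, spacer_len = 100L, min_span = 25L,
                               name = "concat") {
  stopifnot(inherits(assembly, "assembly"))
  records <- assembly$records
  if (length(records) < 1L) stop_data("assembly has no records")
  spacer_len <- as.integer(spacer_len)
  if (spacer_len < min_span) {
    stop(sprintf(
      "spacer_len (%d) is shorter than the longest reportable STR span (%d); an STR could bridge a contig junction",
      spacer_len, as.integer(min_span)
    ), call. = FALSE)
  }
  lens <- nchar(records)
  offsets <- cumsum(c(0L, utils::head(lens + spacer_len, -1L)))
  combined <- paste(records, collapse = strrep("N", spacer_len))
  coord_map <- data.frame(
    contig = names(records),
    offset = as.integer(offsets),
    length = as.integer(lens),
    stringsAsFactors = FALSE
  )
  out <- stats::setNames(combined, name)
  new_assembly(out, dialect = assembly$dialect, coord_map = coord_map)
}

#' Map concatenated coordinates back to contig coordinates
#'
#' @param assembly A concatenated `assembly` (with a `coord_map`).
#' @param pos Integer vector of 0-based positions on the concatenated strand.
#' @return Data frame with columns `contig` and `local_pos` (0-based); spacer
#'   positions map to `NA`.
#' @export
map_concat_position <- function(assembly, pos) {
  cm <- assembly$coord_map
  if (is.null(cm)) stop("assembly has no coordinate map", call. = FALSE)
  idx <- findInterval(pos, cm$offset)
  contig <- rep(NA_character_, length(pos))
  local <- rep(NA_integer_, length(pos))
  inside <- idx >= 1L & pos < cm$offset[pmax(idx, 1L)] + cm$length[pmax(idx, 1L)] &
    pos >= 0L
  contig[inside] <- cm$contig[idx[inside]]
  local[inside] <- as.integer(pos[inside] - cm$offset[idx[inside]])
  data.frame(contig = contig, local_pos = local, stringsAsFactors = FALSE)
}

#' Translate loci found on a concatenated strand to contig coordinates
#'
#' @param loci A locus table from [find_strs()] run on a concatenated assembly.
#' @param assembly The concatenated `assembly` carrying the coordinate map.
#' @return The locus table with `contig`, `start`, `end` rewritten in
#'   per-contig coordinates. Loci that touch spacer positions cannot occur
#'   (N breaks repeat runs) and would be an error.
#' @export
translate_loci <- function(loci, assembly) {
  if (nrow(loci) == 0L) return(loci)
  m_start <- map_concat_position(assembly, loci$start)
  m_end <- map_concat_position(assembly, loci$end - 1L)
  if (anyNA(m_start$contig) || anyNA(m_end$contig) ||
      any(m_start$contig != m_end$contig)) {
    stop("locus overlaps a spacer junction; this should be impossible", call. = FALSE)
  }
  loci$contig <- m_start$contig
  len <- loci$end - loci$start
  loci$start <- m_start$local_pos
  loci$end <- loci$start + len
  loci[order_loci(loci), , drop = FALSE]
}

#' Extract flanking sequence around a repeat locus
#'
#' Returns up to `flank_len` bases immediately to the left and right of a
#' locus, for primer design. Truncation at a contig end is reported via
#' `complete`, never as an error.
#'
#' @param assembly An `assembly` object.
#' @param contig Contig name.
#' @param start,end Locus coordinates, 0-based half-open.
#' @param flank_len Desired flank length in bp (default 300).
#' @return A list with `left`, `right` (character) and `complete` (`TRUE` iff
#'   both flanks have exactly `flank_len` bases).
#' @export
extract_flanks <- function(assembly, contig, start, end, flank_len = 300L) {
  seqs <- if (inherits(assembly, "assembly")) assembly$records else assembly
  if (!contig %in% names(seqs)) {
    stop_data(sprintf("contig '%s' not present in assembly", contig))
  }
  s <- seqs[[contig]]
  n <- nchar(s)
  if (start < 0L || end > n || start >= end) {
    stop_data(sprintf("locus [%d,%d) outside contig '%s' (length %d)", start, end, contig, n))
  }
  left <- substr(s, max(1L, start - flank_len + 1L), start)       # 1-based slice ending at locus start
  right <- substr(s, end + 1L, min(n, end + flank_len))
  list(
    left = left,
    right = right,
    complete = nchar(left) == flank_len && nchar(right) == flank_len
  )
}

# error helpers: data errors exit 1 from the CLI, usage errors exit 2
stop_data <- function(msg) {
  stop(structure(
    class = c("strscreen_data_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_usage <- function(msg) {
  stop(structure(
    class = c("strscreen_usage_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
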