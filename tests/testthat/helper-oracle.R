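# Independent brute-force oracle for the repeat scanner, plus small fixture
# builders. The oracle walks every candidate start position with plain
# character operations (no run-length encoding, no vectorized comparisons),
# so it shares no mechanism with the scanner it checks.

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 4L && substr(motif, 1L, 2L) == substr(motif, 3L, 4L)) return(FALSE)
  first <- substr(motif, 1L, 1L)
  !(strrep(first, k) == motif)
}

oracle_find_strs <- function(seq, unit_sizes = 2:5, min_units = 5L) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (k in unit_sizes) {
    last_start <- n - k * min_units + 1L
    if (last_start < 1L) next
    for (i in seq_len(last_start)) {
      motif <- substr(seq, i, i + k - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      # left maximality: the character before i must not extend the period
      if (i > 1L && ch[i - 1L] != "N" && ch[i - 1L] == ch[i - 1L + k]) next
      if (!oracle_primitive(motif)) next
      m <- i + k
      while (m <= n && ch[m] != "N" && ch[m] == ch[m - k]) m <- m + 1L
      units <- (m - i) %/% k
      if (units >= min_units) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + units * k, motif = motif,
          unit_size = k, units = units, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), motif = character(0),
                      unit_size = integer(0), units = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_size), , drop = FALSE]
}

locus_key <- function(df, contig = NULL) {
  if (nrow(df) == 0L) return(character(0))
  ctg <- if (!is.null(contig)) contig
    else if ("contig" %in% names(df)) df$contig
    else ""
  paste(ctg, df$start, df$end, df$motif, df$unit_size, df$units, sep = "|")
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rand_assembly <- function(n_rec = 3L, len = c(50L, 400L), gc = 0.5) {
  seqs <- vapply(seq_len(n_rec), function(i) {
    rand_seq(sample(seq.int(len[1L], len[2L]), 1L), gc)
  }, character(1))
  names(seqs) <- sprintf("ctg%d", seq_len(n_rec))
  seqs
}

# write a minimal VCF file from parallel vectors; sample fields are
# "GT:AD:DP" strings, one character vector per sample
write_test_vcf <- function(path, contig, pos, ref, alt, qual,
                           samples = NULL, sample_fields = NULL,
                           format = "GT:AD:DP") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (!is.null(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  body <- vapply(seq_along(pos), function(i) {
    fields <- c(contig[i], pos[i], ".", ref[i], alt[i], qual[i], "PASS", ".")
    if (!is.null(samples)) {
      fields <- c(fields, format, vapply(sample_fields, `[[`, character(1), i))
    }
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# plant a repeat run inside a random background, pinning the boundary bases
# so the run is maximal exactly as given; returns the sequence
plant_run <- function(len, motif, units, at, gc = 0.5) {
  s <- rand_seq(len, gc)
  run <- strrep(motif, units)
  k <- nchar(motif)
  s <- paste0(substr(s, 1L, at), run, substr(s, at + nchar(run) + 1L, len))
  pick <- function(not) sample(setdiff(c("A", "C", "G", "T"), not), 1L)
  substr(s, at, at) <- pick(substr(motif, k, k))
  substr(s, at + nchar(run) + 1L, at + nchar(run) + 1L) <- pick(substr(motif, 1L, 1L))
  s
}

small_config <- function(...) str_config(flank_len = 30L, min_depth = 8L, ...)

new_assembly_for_test <- function(records, dialect = "fasta") {
  structure(list(records = records, dialect = dialect, coord_map = NULL),
            class = "assembly")
}
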