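# VCF record handling: parsing with multi-allelic splitting, SNP/indel
# classification, and left-normalization of indels against the assembly.
# The container is deliberately plain: a `vcf_set` is a list of two data
# frames, `variants` (one row per contig/pos/ref/alt after splitting) and
# `support` (one row per variant x sample with ref/alt read depths).

new_vcf_set <- function(variants, support, samples, n_skipped = 0L) {
  structure(
    list(variants = variants, support = support, samples = samples,
         n_skipped = n_skipped),
    class = "vcf_set"
  )
}

#' @export
print.vcf_set <- function(x, ...) {
  cat(sprintf(
    "VCF set: %d variant%s (%d SNP, %d indel, %d other), samples: %s\n",
    nrow(x$variants), if (nrow(x$variants) == 1L) "" else "s",
    sum(x$variants$kind == "SNP"), sum(x$variants$kind == "INDEL"),
    sum(x$variants$kind == "OTHER"), paste(x$samples, collapse = ", ")
  ))
  invisible(x)
}

empty_variants <- function() {
  data.frame(
    var_id = integer(0), contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), qual = numeric(0),
    kind = character(0), length_delta = integer(0), filter = character(0),
    stringsAsFactors = FALSE
  )
}

# classify an allele pair: SNP, INDEL (one allele is the other plus a
# contiguous inserted/deleted block), or OTHER (MNP / complex substitution)
classify_kind <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  if (nr == 1L && na == 1L) return(if (ref == alt) "OTHER" else "SNP")
  if (nr == na) return("OTHER")
  # strip longest common prefix, then longest common suffix of the remainder
  p <- common_prefix_len(ref, alt)
  r2 <- substr(ref, p + 1L, nr)
  a2 <- substr(alt, p + 1L, na)
  s <- common_suffix_len(r2, a2)
  if (nchar(r2) - s == 0L || nchar(a2) - s == 0L) "INDEL" else "OTHER"
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L)) i <- i + 1L
  i
}

common_suffix_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  i <- 0L
  while (i < n && substr(a, na - i, na - i) == substr(b, nb - i, nb - i)) i <- i + 1L
  i
}

#' Parse a VCF file
#'
#' Reads a VCF 4.x text file (plain or gzipped), splits multi-allelic records
#' into one variant per alternate allele (re-slicing the AD field per allele),
#' classifies each as SNP / INDEL / OTHER, and extracts per-sample allele
#' support. Symbolic alternates (`<DEL>`, breakends) are skipped with a
#' warning. When AD is absent, support is derived from the genotype call
#' (allele occurrence counts) with a warning, since pooled-library depths are
#' then unknown.
#'
#' @param path Path to the VCF (optionally `.gz`).
#' @return A `vcf_set`: list with `variants` (data frame: `var_id`, `contig`,
#'   `pos` 1-based, `ref`, `alt`, `qual` (`NA` when missing), `kind`,
#'   `length_delta`, `filter`), `support` (data frame: `var_id`, `sample`,
#'   `gt`, `ref_count`, `alt_count`, `depth`) and `samples`.
#' @export
parse_vcf <- function(path) {
  lines <- read_lines_any(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0L) {
    stop_data(sprintf("'%s' has no #CHROM header line; not a valid VCF", path))
  }
  hdr <- hdr[1L]
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 8L) {
    stop_data(sprintf("'%s': #CHROM header has fewer than 8 columns", path))
  }
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  body_idx <- body_idx[body_idx > hdr]

  variants <- vector("list", length(body_idx))
  support <- vector("list", length(body_idx))
  n_skipped <- 0L
  gt_derived <- FALSE
  vid <- 0L

  for (ii in seq_along(body_idx)) {
    ln <- body_idx[ii]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) {
      stop_data(sprintf("'%s' line %d: expected >= 8 tab-separated fields, found %d",
                        path, ln, length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos)) {
      stop_data(sprintf("'%s' line %d: POS '%s' is not an integer", path, ln, f[2L]))
    }
    ref <- toupper(f[4L])
    if (grepl("[^ACGTN]", ref)) {
      stop_data(sprintf("'%s' line %d: REF allele '%s' contains illegal characters",
                        path, ln, f[4L]))
    }
    alts <- strsplit(toupper(f[5L]), ",", fixed = TRUE)[[1L]]
    qual <- if (f[6L] == "." || f[6L] == "") NA_real_ else suppressWarnings(as.numeric(f[6L]))
    fmt <- if (length(f) >= 9L) strsplit(f[9L], ":", fixed = TRUE)[[1L]] else character(0)
    sample_fields <- if (length(samples) > 0L) {
      if (length(f) < 9L + length(samples)) {
        stop_data(sprintf("'%s' line %d: fewer sample columns than header samples", path, ln))
      }
      lapply(f[10:(9L + length(samples))], function(s) strsplit(s, ":", fixed = TRUE)[[1L]])
    } else list()

    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (grepl("[][<>]", alt) || alt == "*") {
        n_skipped <- n_skipped + 1L
        next
      }
      if (grepl("[^ACGTN]", alt)) {
        stop_data(sprintf("'%s' line %d: ALT allele '%s' contains illegal characters",
                          path, ln, alt))
      }
      vid <- vid + 1L
      variants[[length(variants) + 1L]] <- data.frame(
        var_id = vid, contig = f[1L], pos = pos, ref = ref, alt = alt,
        qual = qual, kind = classify_kind(ref, alt),
        length_delta = nchar(alt) - nchar(ref),
        filter = if (length(f) >= 7L) f[7L] else ".",
        stringsAsFactors = FALSE
      )
      for (si in seq_along(samples)) {
        sup <- parse_sample_support(fmt, sample_fields[[si]], ai, length(alts))
        if (sup$from_gt) gt_derived <- TRUE
        support[[length(support) + 1L]] <- data.frame(
          var_id = vid, sample = samples[si], gt = sup$gt,
          ref_count = sup$ref_count, alt_count = sup$alt_count,
          depth = sup$depth, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d symbolic/spanning-deletion alternate allele(s) in '%s'",
                    n_skipped, path), call. = FALSE)
  }
  if (gt_derived) {
    warning(sprintf(
      "AD field absent for some records in '%s'; allele support derived from genotype calls (depths unknown, unreliable for pooled libraries)", path
    ), call. = FALSE)
  }
  variants <- do.call(rbind, c(list(empty_variants()), Filter(Negate(is.null), variants)))
  support <- do.call(rbind, c(
    list(data.frame(var_id = integer(0), sample = character(0), gt = character(0),
                    ref_count = integer(0), alt_count = integer(0),
                    depth = integer(0), stringsAsFactors = FALSE)),
    Filter(Negate(is.null), support)
  ))
  rownames(variants) <- NULL
  rownames(support) <- NULL
  new_vcf_set(variants, support, samples, n_skipped)
}

# Extract support for alternate allele `ai` (1-based among `n_alt`) from one
# sample's FORMAT fields. Prefers AD; falls back to GT occurrence counts.
parse_sample_support <- function(fmt, fields, ai, n_alt) {
  get <- function(key) {
    i <- match(key, fmt)
    if (is.na(i) || i > length(fields)) NA_character_ else fields[i]
  }
  gt <- get("GT")
  ad <- get("AD")
  dp <- suppressWarnings(as.integer(get("DP")))
  if (!is.na(ad) && ad != ".") {
    adv <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1L]]))
    ref_count <- if (length(adv) >= 1L) adv[1L] else NA_integer_
    alt_count <- if (length(adv) >= 1L + ai) adv[1L + ai] else NA_integer_
    depth <- if (!is.na(dp)) dp else sum(adv, na.rm = TRUE)
    return(list(gt = gt %||na% ".", ref_count = ref_count %||na% 0L,
                alt_count = alt_count %||na% 0L, depth = depth, from_gt = FALSE))
  }
  # GT fallback: count allele occurrences in the call
  ref_count <- 0L; alt_count <- 0L
  if (!is.na(gt) && gt != ".") {
    alleles <- strsplit(gt, "[/|]")[[1L]]
    ref_count <- sum(alleles == "0")
    alt_count <- sum(alleles == as.character(ai))
  }
  list(gt = gt %||na% ".", ref_count = as.integer(ref_count),
       alt_count = as.integer(alt_count),
       depth = if (!is.na(dp)) dp else ref_count + alt_count, from_gt = TRUE)
}

`%||na%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Keep only indel variants
#'
#' @param vcf A `vcf_set` from [parse_vcf()].
#' @return A `vcf_set` restricted to `kind == "INDEL"`, order preserved.
#' @export
select_indels <- function(vcf) {
  keep <- vcf$variants$kind == "INDEL"
  ids <- vcf$variants$var_id[keep]
  new_vcf_set(
    vcf$variants[keep, , drop = FALSE],
    vcf$support[vcf$support$var_id %in% ids, , drop = FALSE],
    vcf$samples, vcf$n_skipped
  )
}

#' Left-normalize an indel against the assembly
#'
#' Shifts an insertion/deletion to its leftmost equivalent representation and
#' trims it to the minimal prefix-anchored form (one shared anchor base,
#' then the inserted or deleted block). The edited sequence is unchanged;
#' the operation is idempotent. Different variant callers place indels at
#' different positions within a repeat run, so normalization is required
#' before intersecting indels with repeat loci.
#'
#' @param contig,pos,ref,alt One VCF indel (pos 1-based).
#' @param assembly The `assembly` the VCF was called against.
#' @return A list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_indel <- function(contig, pos, ref, alt, assembly) {
  seqs <- if (inherits(assembly, "assembly")) assembly$records else assembly
  if (!contig %in% names(seqs)) {
    stop_data(sprintf("variant contig '%s' not present in assembly", contig))
  }
  s <- seqs[[contig]]
  if (classify_kind(ref, alt) != "INDEL") {
    stop("normalize_indel() requires an indel allele pair", call. = FALSE)
  }
  if (substr(s, pos, pos + nchar(ref) - 1L) != ref) {
    stop_data(sprintf(
      "REF allele mismatch at %s:%d: VCF says '%s', assembly has '%s' (wrong assembly for this VCF?)",
      contig, pos, ref, substr(s, pos, pos + nchar(ref) - 1L)
    ))
  }
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    changed <- FALSE
    while (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt) &&
           !(nchar(ref) == 1L && nchar(alt) == 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 1L) {
        # cannot extend left of the contig; re-anchor on the right instead
        b <- substr(s, pos + nchar(ref), pos + nchar(ref))
        ref <- paste0(ref, b)
        alt <- paste0(alt, b)
        break
      }
      pos <- pos - 1L
      b <- substr(s, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  # trim shared leading bases down to a single anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         substr(ref, 2L, 2L) == substr(alt, 2L, 2L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-normalize all indels in a `vcf_set`
#'
#' @param vcf A `vcf_set` containing only indels (see [select_indels()]).
#' @param assembly The matching `assembly`.
#' @return The `vcf_set` with `pos`, `ref`, `alt` rewritten in normalized form.
#' @export
normalize_indels <- function(vcf, assembly) {
  v <- vcf$variants
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] != "INDEL") next
    nz <- normalize_indel(v$contig[i], v$pos[i], v$ref[i], v$alt[i], assembly)
    v$pos[i] <- nz$pos
    v$ref[i] <- nz$ref
    v$alt[i] <- nz$alt
  }
  vcf$variants <- v
  vcf
}

#' Apply one variant to a contig sequence
#'
#' Utility used to check that two representations of an indel are equivalent:
#' substitutes `alt` for `ref` at `pos` and returns the edited sequence.
#'
#' @param seq Contig sequence.
#' @param pos 1-based position of the REF allele.
#' @param ref,alt Allele strings.
#' @return The edited sequence.
#' @export
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

#' Write a `vcf_set` (or raw record table) as a VCF file
#'
#' Each variant row becomes one bi-allelic record with `GT:AD:DP` sample
#' fields. Used by the simulator and for round-trip testing.
#'
#' @param vcf A `vcf_set`.
#' @param path Output path; `.gz` triggers compression.
#' @param contig_lengths Optional named integer vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, contig_lengths = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=strscreen",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths), contig_lengths)
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(vcf$samples) > 0L) c("FORMAT", vcf$samples)),
          collapse = "\t")
  ), con)
  v <- vcf$variants
  for (i in seq_len(nrow(v))) {
    qual <- if (is.na(v$qual[i])) "." else format(v$qual[i], scientific = FALSE)
    fields <- c(v$contig[i], v$pos[i], ".", v$ref[i], v$alt[i], qual,
                v$filter[i] %||na% ".", ".")
    if (length(vcf$samples) > 0L) {
      sup <- vcf$support[vcf$support$var_id == v$var_id[i], , drop = FALSE]
      sup <- sup[match(vcf$samples, sup$sample), , drop = FALSE]
      fields <- c(fields, "GT:AD:DP", sprintf(
        "%s:%d,%d:%d", sup$gt, sup$ref_count, sup$alt_count, sup$depth
      ))
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
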