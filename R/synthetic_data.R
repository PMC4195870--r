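# Synthetic genome + pooled-library VCF simulator with an exact truth table.
# The background is i.i.d. random sequence scrubbed (by rejection) of any
# accidental repeat that the scanner would report, so the truth table is
# exact rather than probabilistic: every reportable repeat was planted, and
# each planted locus's expected pipeline verdict follows from its planted
# parameters and the configuration alone. No read-level simulation is done;
# the VCF is fabricated directly with per-pool allele depths.

PLANT_TYPES <- c("poly", "fixed", "mono", "trap_nonmult", "trap_lowqual", "trap_flankn")

#' Plan a set of loci to plant
#'
#' Draws motifs, repeat counts, indel deltas and per-population allele
#' fractions for a set of planted loci, using the current RNG state. Types:
#' `poly` (unit-multiple indels, both pools at intermediate frequency),
#' `fixed` (one pool at frequency 1.0, the other at 0.3, so the locus is
#' polymorphic overall but fixed in one target population), `mono` (no indel:
#' the locus must never be reported), and three trap types that are planted to
#' fail exactly one candidate filter: `trap_nonmult` (indel length not a unit
#' multiple), `trap_lowqual` (supporting record below the QUAL threshold),
#' `trap_flankn` (an N call inside the 300 bp flank window).
#'
#' @param n_poly,n_fixed,n_mono,n_trap_nonmult,n_trap_lowqual,n_trap_flankn
#'   Number of loci of each type.
#' @param pops Population (pool) names.
#' @param unit_size Repeat unit size of planted loci (default 3).
#' @param units_range Range of planted repeat counts (default 6 to 20).
#' @return Data frame with one row per planted locus: `id`, `type`, `motif`,
#'   `unit_size`, `units`, `deltas` (list column, bp), `qual_class`, and one
#'   `freq_<pop>` list column of planted per-allele alternate fractions.
#' @export
plan_planted_loci <- function(n_poly = 30L, n_fixed = 10L, n_mono = 10L,
                              n_trap_nonmult = 4L, n_trap_lowqual = 3L,
                              n_trap_flankn = 3L, pops = c("popA", "popB"),
                              unit_size = 3L, units_range = c(6L, 20L)) {
  unit_size <- as.integer(unit_size)
  type <- rep(
    c("poly", "fixed", "mono", "trap_nonmult", "trap_lowqual", "trap_flankn"),
    times = c(n_poly, n_fixed, n_mono, n_trap_nonmult, n_trap_lowqual, n_trap_flankn)
  )
  n <- length(type)
  motifs <- all_primitive_motifs(unit_size)
  plan <- data.frame(
    id = sprintf("L%03d", seq_len(n)),
    type = type,
    motif = sample(motifs, n, replace = TRUE),
    unit_size = unit_size,
    units = sample(seq.int(units_range[1L], units_range[2L]), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  plan$deltas <- lapply(seq_len(n), function(i) {
    k <- unit_size
    u <- plan$units[i]
    tp <- plan$type[i]
    if (tp == "mono") return(integer(0))
    if (tp == "trap_nonmult") {
      # one unit plus one extra base: never a unit multiple for k >= 2
      return(k + 1L)
    }
    n_alleles <- if (tp == "poly" && stats::runif(1) < 0.5) 2L else 1L
    choices <- setdiff(seq.int(-min(4L, u - 1L), 4L), 0L)
    du <- sample(choices, n_alleles)
    as.integer(du * k)
  })
  plan$qual_class <- ifelse(plan$type == "trap_lowqual", "low", "normal")
  for (p in pops) {
    plan[[paste0("freq_", p)]] <- lapply(seq_len(n), function(i) {
      nd <- length(plan$deltas[[i]])
      if (nd == 0L) return(numeric(0))
      if (plan$type[i] == "fixed") {
        # first pool fixed for the alternate allele, second intermediate
        if (p == pops[1L]) 1.0 else 0.3
      } else {
        total <- stats::runif(1, 0.25, 0.75)
        if (nd == 1L) total else total * c(0.6, 0.4)
      }
    })
  }
  plan
}

all_primitive_motifs <- function(k) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), k), stringsAsFactors = FALSE))
  motifs <- do.call(paste0, grid)
  motifs[is_primitive(motifs)]
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# replace the 0-based positions `pos0` of `seq` with fresh random bases
patch_positions <- function(seq, pos0, gc) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ch[pos0 + 1L] <- sample(c("A", "T", "G", "C"), length(pos0), replace = TRUE,
                          prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  paste(ch, collapse = "")
}

set_base <- function(seq, pos0, base) {
  paste0(substr(seq, 1L, pos0), base, substr(seq, pos0 + 2L, nchar(seq)))
}

#' Generate a synthetic genome with planted repeat loci
#'
#' Builds `n_contigs` random contigs, removes every accidental repeat the
#' scanner would report (rejection scrubbing), then plants the planned loci at
#' well-separated positions, pins the bases adjacent to each run so the
#' planted run is maximal exactly as specified, plants the flank `N` of
#' `trap_flankn` loci, and verifies that a scan recovers exactly the planted
#' set.
#'
#' @param plan Output of [plan_planted_loci()] (or `NULL` for a plain
#'   repeat-free background).
#' @param n_contigs,contig_len,gc Background shape: contig count, length (bp),
#'   GC content.
#' @param config An [str_config()]; defines what counts as a reportable repeat.
#' @param seed Integer seed fixing all randomness.
#' @return A list with `assembly` and `truth` (the plan plus realized `contig`,
#'   `start`, `end` 0-based half-open and `n_pos` for planted flank Ns).
#' @export
generate_genome <- function(plan = NULL, n_contigs = 4L, contig_len = 50000L,
                            gc = 0.5, config = str_config(), seed = 1L) {
  set.seed(seed)
  n_loci <- if (is.null(plan)) 0L else nrow(plan)
  margin <- config$flank_len + 60L
  max_span <- if (n_loci > 0L) max(plan$units * plan$unit_size) else 0L
  if (n_loci > 0L) {
    per_contig <- ceiling(n_loci / n_contigs)
    spacing <- (contig_len - 2 * margin) / per_contig
    if (spacing < 2 * config$flank_len + max_span + 20L) {
      stop(sprintf(
        "infeasible packing: %d loci need ~%d bp each but contigs allow %.0f bp per locus",
        n_loci, 2L * config$flank_len + max_span + 20L, spacing
      ), call. = FALSE)
    }
  }

  contigs <- stats::setNames(
    vapply(seq_len(n_contigs), function(i) random_seq(contig_len, gc), character(1)),
    sprintf("ctg%02d", seq_len(n_contigs))
  )
  contigs <- scrub_accidental_strs(contigs, config, gc)

  truth <- if (is.null(plan)) NULL else plan
  if (n_loci > 0L) {
    slot_contig <- rep(seq_len(n_contigs), length.out = n_loci)
    slot_rank <- stats::ave(seq_len(n_loci), slot_contig, FUN = seq_along)
    per_contig <- tabulate(slot_contig, n_contigs)
    truth$contig <- names(contigs)[slot_contig]
    truth$start <- NA_integer_
    truth$end <- NA_integer_
    truth$n_pos <- NA_integer_
    for (i in seq_len(n_loci)) {
      ci <- slot_contig[i]
      spacing <- (contig_len - 2 * margin) / per_contig[ci]
      base_pos <- margin + floor((slot_rank[i] - 0.5) * spacing)
      start0 <- as.integer(base_pos + sample.int(41L, 1L) - 21L)  # small jitter
      run <- strrep(truth$motif[i], truth$units[i])
      span <- nchar(run)
      s <- contigs[[ci]]
      s <- paste0(substr(s, 1L, start0), run, substr(s, start0 + span + 1L, nchar(s)))
      # pin the boundary bases so the planted run is maximal exactly as planned,
      # and (for the non-unit-multiple trap) so the fabricated insertion is
      # already left-normalized and cannot shift out of the assignment window
      k <- truth$unit_size[i]
      motif_chars <- strsplit(truth$motif[i], "", fixed = TRUE)[[1L]]
      forbid_left <- motif_chars[k]
      if (truth$type[i] == "trap_nonmult") {
        m <- (k + 1L) %% k  # = 1
        forbid_left <- c(forbid_left, motif_chars[m])
      }
      s <- set_base(s, start0 - 1L, sample(setdiff(c("A", "C", "G", "T"), forbid_left), 1L))
      s <- set_base(s, start0 + span, sample(setdiff(c("A", "C", "G", "T"), motif_chars[1L]), 1L))
      contigs[[ci]] <- s
      truth$start[i] <- start0
      truth$end[i] <- start0 + span
      if (truth$type[i] == "trap_flankn") {
        npos <- start0 - (20L + sample.int(config$flank_len - 40L, 1L))
        contigs[[ci]] <- set_base(contigs[[ci]], npos, "N")
        truth$n_pos[i] <- npos
      }
    }
    contigs <- verify_and_fix_planting(contigs, truth, config, gc)
  }
  list(assembly = new_assembly(contigs, dialect = "fasta"), truth = truth)
}

scrub_accidental_strs <- function(contigs, config, gc, protect = NULL, max_iter = 100L) {
  for (iter in seq_len(max_iter)) {
    loci <- find_strs(contigs, config)
    if (!is.null(protect)) {
      planted <- paste(protect$contig, protect$start, protect$end, protect$motif)
      found <- paste(loci$contig, loci$start, loci$end, loci$motif)
      loci <- loci[!found %in% planted, , drop = FALSE]
    }
    if (nrow(loci) == 0L) return(contigs)
    for (ci in unique(loci$contig)) {
      sel <- loci[loci$contig == ci, , drop = FALSE]
      pos0 <- unlist(lapply(seq_len(nrow(sel)), function(r) seq.int(sel$start[r], sel$end[r] - 1L)))
      if (!is.null(protect)) {
        prot <- protect[protect$contig == ci, , drop = FALSE]
        keep_out <- unlist(lapply(seq_len(nrow(prot)), function(r) {
          seq.int(prot$start[r] - 1L, prot$end[r])
        }))
        keep_out <- c(keep_out, prot$n_pos[!is.na(prot$n_pos)])
        pos0 <- setdiff(pos0, keep_out)
      }
      if (length(pos0) > 0L) contigs[[ci]] <- patch_positions(contigs[[ci]], pos0, gc)
    }
  }
  stop("failed to scrub accidental repeats after 100 iterations", call. = FALSE)
}

verify_and_fix_planting <- function(contigs, truth, config, gc) {
  contigs <- scrub_accidental_strs(contigs, config, gc, protect = truth)
  loci <- find_strs(contigs, config)
  planted <- paste(truth$contig, truth$start, truth$end, truth$motif)
  found <- paste(loci$contig, loci$start, loci$end, loci$motif)
  if (!setequal(planted, found)) {
    stop("planted loci could not be realized exactly; adjust the plan", call. = FALSE)
  }
  contigs
}

#' Fabricate a pooled-library VCF for planted loci
#'
#' Writes one or more indel records per polymorphic planted locus (anchored one
#' base left of the run, already left-normalized), with per-pool `AD` depths
#' drawn around `depth_mean` and alternate counts matching the planted allele
#' fractions; QUAL is drawn from a high-quality distribution except for
#' `trap_lowqual` loci. Two-allele loci are emitted as one multi-allelic
#' record when both alleles are insertions (exercising multi-allelic
#' splitting downstream), otherwise as separate records at the same position.
#' Decoy SNPs and off-locus decoy indels are added; neither can become a
#' candidate.
#'
#' @param truth Truth table from [generate_genome()].
#' @param assembly The matching `assembly`.
#' @param path Output VCF path.
#' @param pops Population names (VCF sample columns).
#' @param depth_mean Mean pool depth per record (floor 12 so that rounding
#'   cannot move a planted fraction across the fixation thresholds).
#' @param seed Integer seed.
#' @param multiallelic_frac Fraction of eligible two-allele loci emitted as a
#'   single multi-allelic record.
#' @param n_decoy_snps,n_decoy_indels Decoy record counts.
#' @return `path`, invisibly.
#' @export
generate_vcf <- function(truth, assembly, path, pops = c("popA", "popB"),
                         depth_mean = 30L, seed = 1L, multiallelic_frac = 0.5,
                         n_decoy_snps = 40L, n_decoy_indels = 10L) {
  set.seed(seed)
  seqs <- assembly$records
  recs <- list()

  draw_depth <- function() max(12L, stats::rpois(1L, depth_mean))
  draw_qual <- function(class) {
    if (class == "low") round(stats::runif(1, 3, 10), 1)
    else round(min(150, max(25, stats::rnorm(1, 80, 15))), 1)
  }
  sample_fields <- function(fracs) {
    # fracs: per-alt planted fractions for one pool
    vapply(seq_along(pops), function(pi) {
      depth <- draw_depth()
      alt <- vapply(fracs[[pi]], function(f) as.integer(round(depth * f)), integer(1))
      ref <- depth - sum(alt)
      gt <- if (all(alt == 0L)) "0/0"
        else if (ref == 0L && length(alt) == 1L) "1/1"
        else "0/1"
      sprintf("%s:%s:%d", gt, paste(c(ref, alt), collapse = ","), depth)
    }, character(1))
  }

  for (i in seq_len(nrow(truth))) {
    deltas <- truth$deltas[[i]]
    if (length(deltas) == 0L) next
    s <- seqs[[truth$contig[i]]]
    start0 <- truth$start[i]
    pos <- start0                       # 1-based anchor = base before the run
    anchor <- substr(s, pos, pos)
    run <- strrep(truth$motif[i], truth$units[i])
    alleles <- lapply(deltas, function(d) {
      if (d > 0L) {
        list(ref = anchor,
             alt = paste0(anchor, substr(strrep(truth$motif[i], ceiling(d / truth$unit_size[i]) + 1L), 1L, d)))
      } else {
        list(ref = paste0(anchor, substr(run, 1L, -d)), alt = anchor)
      }
    })
    fracs_by_pop <- lapply(pops, function(p) truth[[paste0("freq_", p)]][[i]])
    qual <- draw_qual(truth$qual_class[i])
    merge_ok <- length(deltas) == 2L && all(deltas > 0L) &&
      stats::runif(1) < multiallelic_frac
    if (merge_ok) {
      recs[[length(recs) + 1L]] <- list(
        contig = truth$contig[i], pos = pos, ref = anchor,
        alt = paste(vapply(alleles, `[[`, character(1), "alt"), collapse = ","),
        qual = qual,
        samples = sample_fields(fracs_by_pop)
      )
    } else {
      for (j in seq_along(deltas)) {
        recs[[length(recs) + 1L]] <- list(
          contig = truth$contig[i], pos = pos, ref = alleles[[j]]$ref,
          alt = alleles[[j]]$alt, qual = draw_qual(truth$qual_class[i]),
          samples = sample_fields(lapply(fracs_by_pop, function(f) f[j]))
        )
      }
    }
  }

  # decoy records, kept clear of every planted window
  windows <- if (nrow(truth) > 0L) truth else NULL
  clear_of_loci <- function(contig, pos0, pad = 30L) {
    if (is.null(windows)) return(TRUE)
    w <- windows[windows$contig == contig, , drop = FALSE]
    all(pos0 + pad < w$start | pos0 - pad > w$end)
  }
  bases <- c("A", "C", "G", "T")
  add_decoys <- function(n, indel) {
    added <- 0L
    guard <- 0L
    while (added < n && guard < n * 50L) {
      guard <- guard + 1L
      ctg <- sample(names(seqs), 1L)
      pos <- sample.int(nchar(seqs[[ctg]]) - 20L, 1L) + 5L
      if (!clear_of_loci(ctg, pos - 1L)) next
      ref1 <- substr(seqs[[ctg]], pos, pos + (if (indel) 3L else 0L))
      if (grepl("N", ref1, fixed = TRUE)) next
      alt1 <- if (indel) substr(ref1, 1L, 1L) else sample(setdiff(bases, ref1), 1L)
      f <- stats::runif(1, 0.2, 0.8)
      recs[[length(recs) + 1L]] <<- list(
        contig = ctg, pos = pos, ref = ref1, alt = alt1,
        qual = draw_qual("normal"),
        samples = sample_fields(rep(list(f), length(pops)))
      )
      added <- added + 1L
    }
  }
  add_decoys(n_decoy_snps, indel = FALSE)
  add_decoys(n_decoy_indels, indel = TRUE)

  ord <- order(vapply(recs, `[[`, character(1), "contig"),
               vapply(recs, function(r) as.numeric(r$pos), numeric(1)),
               method = "radix")
  recs <- recs[ord]

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=strscreen-simulate",
    sprintf("##contig=<ID=%s,length=%d>", names(seqs), nchar(seqs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", pops),
          collapse = "\t")
  ), con)
  for (rec in recs) {
    writeLines(paste(c(rec$contig, rec$pos, ".", rec$ref, rec$alt,
                       format(rec$qual, scientific = FALSE), "PASS", ".",
                       "GT:AD:DP", rec$samples), collapse = "\t"), con)
  }
  invisible(path)
}

#' Compute the expected pipeline verdict for every planted locus
#'
#' The verdict follows from the planted parameters and the configuration by
#' the documented screening rules: monomorphic loci are absent (no indel ever
#' reaches them); trap loci are excluded with their planted reason; all other
#' loci are candidates; `fixed` loci additionally appear in the fixed list.
#'
#' @param truth Truth table from [generate_genome()].
#' @param config An [str_config()].
#' @return `truth` with `expected_verdict`, `expected_reason` and
#'   `expected_fixed` columns.
#' @export
expected_verdicts <- function(truth, config = str_config()) {
  truth$expected_verdict <- vapply(seq_len(nrow(truth)), function(i) {
    switch(truth$type[i],
      mono = "absent",
      trap_nonmult = ,
      trap_lowqual = ,
      trap_flankn = "excluded",
      if (!truth$unit_size[i] %in% config$candidate_motif_sizes) "excluded" else "candidate"
    )
  }, character(1))
  truth$expected_reason <- vapply(seq_len(nrow(truth)), function(i) {
    switch(truth$type[i],
      trap_nonmult = "non-unit-multiple",
      trap_lowqual = "low-qual",
      trap_flankn = "flank-N",
      if (truth$expected_verdict[i] == "excluded") "motif-size" else ""
    )
  }, character(1))
  truth$expected_fixed <- truth$type == "fixed"
  truth
}

#' Simulate a complete dataset: genome, VCF and truth table
#'
#' Convenience wrapper: plans loci, generates the genome and VCF, attaches
#' expected verdicts, and (optionally) writes `ref.fa`, `calls.vcf` and
#' `truth.tsv` into `out_dir`.
#'
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param seed Integer seed fixing all randomness.
#' @param pops Population names.
#' @param n_contigs,contig_len,gc Genome shape.
#' @param n_poly,n_fixed,n_mono,n_trap_nonmult,n_trap_lowqual,n_trap_flankn
#'   Planted locus counts by type (see [plan_planted_loci()]).
#' @param depth_mean Mean pool depth.
#' @param config An [str_config()].
#' @param ... Passed to [generate_vcf()].
#' @return A list with `assembly`, `truth` (verdicts attached) and `paths`.
#' @export
simulate_dataset <- function(out_dir = NULL, seed = 1L, pops = c("popA", "popB"),
                             n_contigs = 4L, contig_len = 50000L, gc = 0.5,
                             n_poly = 30L, n_fixed = 10L, n_mono = 10L,
                             n_trap_nonmult = 4L, n_trap_lowqual = 3L,
                             n_trap_flankn = 3L, depth_mean = 30L,
                             config = str_config(), ...) {
  set.seed(seed)
  plan <- plan_planted_loci(
    n_poly = n_poly, n_fixed = n_fixed, n_mono = n_mono,
    n_trap_nonmult = n_trap_nonmult, n_trap_lowqual = n_trap_lowqual,
    n_trap_flankn = n_trap_flankn, pops = pops
  )
  gen <- generate_genome(plan, n_contigs = n_contigs, contig_len = contig_len,
                         gc = gc, config = config, seed = seed + 1L)
  truth <- expected_verdicts(gen$truth, config)
  paths <- NULL
  vcf_path <- tempfile(fileext = ".vcf")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vcf_path <- file.path(out_dir, "calls.vcf")
  }
  generate_vcf(truth, gen$assembly, vcf_path, pops = pops,
               depth_mean = depth_mean, seed = seed + 2L, ...)
  if (!is.null(out_dir)) {
    fa_path <- file.path(out_dir, "ref.fa")
    write_assembly(gen$assembly, fa_path)
    truth_path <- file.path(out_dir, "truth.tsv")
    write_truth_tsv(truth, truth_path, pops)
    paths <- list(fasta = fa_path, vcf = vcf_path, truth = truth_path)
  } else {
    paths <- list(fasta = NULL, vcf = vcf_path, truth = NULL)
  }
  list(assembly = gen$assembly, truth = truth, paths = paths)
}

write_truth_tsv <- function(truth, path, pops) {
  flat <- truth
  flat$deltas <- vapply(truth$deltas, paste, character(1), collapse = ",")
  for (p in pops) {
    col <- paste0("freq_", p)
    flat[[col]] <- vapply(truth[[col]], paste, character(1), collapse = ",")
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
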