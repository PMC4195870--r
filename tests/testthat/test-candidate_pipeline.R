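# build a small assembly + matched pstr table around hand-planted loci
make_pipeline_fixture <- function(seed = 41L) {
  set.seed(seed)
  cfg <- str_config()
  plan <- plan_planted_loci(n_poly = 6, n_fixed = 2, n_mono = 0,
                            n_trap_nonmult = 1, n_trap_lowqual = 1,
                            n_trap_flankn = 1)
  gen <- generate_genome(plan, n_contigs = 2L, contig_len = 12000L, seed = seed)
  vcf_path <- tempfile(fileext = ".vcf")
  generate_vcf(gen$truth, gen$assembly, vcf_path, seed = seed + 1L)
  vcf <- parse_vcf(vcf_path)
  indels <- normalize_indels(select_indels(vcf), gen$assembly)
  loci <- find_strs(gen$assembly, cfg)
  pstrs <- population_status(assign_indels(loci, indels, cfg), vcf, cfg)
  list(cfg = cfg, assembly = gen$assembly, truth = expected_verdicts(gen$truth, cfg),
       pstrs = pstrs, vcf = vcf)
}

test_that("filters partition the input and report the first failing rule", {
  fx <- make_pipeline_fixture()
  flt <- filter_candidates(fx$pstrs, fx$assembly, fx$cfg)
  expect_equal(nrow(flt$kept) + nrow(flt$excluded), nrow(fx$pstrs))
  expect_true(all(flt$excluded$exclusion_reason %in%
                    c("motif-size", "low-qual", "flank-N", "non-unit-multiple")))
  # planted traps carry their planted reason
  key <- function(df) paste(df$contig, df$start)
  tr <- fx$truth[fx$truth$expected_verdict == "excluded", ]
  got <- flt$excluded$exclusion_reason[match(key(tr), key(flt$excluded))]
  expect_equal(got, tr$expected_reason)
})

test_that("a di-nucleotide locus fails the motif-size filter first", {
  set.seed(42)
  s <- plant_run(2000L, "AT", 8L, at = 900L)
  assembly <- new_assembly_for_test(c(c1 = s))
  loci <- find_strs(assembly, str_config())
  loci <- loci[loci$motif == "AT" & loci$start == 900L, ]
  ind <- structure(list(
    variants = data.frame(var_id = 1L, contig = "c1", pos = 900L, ref = "G",
                          alt = "GAT", qual = 5, kind = "INDEL",
                          length_delta = 2L, filter = "PASS",
                          stringsAsFactors = FALSE),
    support = data.frame(var_id = 1L, sample = "p", gt = "0/1",
                         ref_count = 10L, alt_count = 10L, depth = 20L,
                         stringsAsFactors = FALSE),
    samples = "p", n_skipped = 0L), class = "vcf_set")
  cfg <- str_config()
  ps <- population_status(assign_indels(loci, ind, cfg), ind, cfg)
  flt <- filter_candidates(ps, assembly, cfg)
  # qual is also low, but motif-size is the first rule in the order
  expect_equal(flt$excluded$exclusion_reason, "motif-size")
})

test_that("an N within the flank window excludes a candidate", {
  set.seed(43)
  s <- plant_run(2000L, "ATC", 8L, at = 900L)
  substr(s, 900L + 24L + 251L, 900L + 24L + 251L) <- "N"  # 250 bp downstream
  assembly <- new_assembly_for_test(c(c1 = s))
  loci <- find_strs(assembly, str_config())
  loci <- loci[loci$start == 900L, ]
  ind <- structure(list(
    variants = data.frame(var_id = 1L, contig = "c1", pos = 900L, ref = "G",
                          alt = "GATC", qual = 99, kind = "INDEL",
                          length_delta = 3L, filter = "PASS",
                          stringsAsFactors = FALSE),
    support = data.frame(var_id = 1L, sample = "p", gt = "0/1",
                         ref_count = 10L, alt_count = 10L, depth = 20L,
                         stringsAsFactors = FALSE),
    samples = "p", n_skipped = 0L), class = "vcf_set")
  cfg <- str_config()
  ps <- population_status(assign_indels(loci, ind, cfg), ind, cfg)
  flt <- filter_candidates(ps, assembly, cfg)
  expect_equal(flt$excluded$exclusion_reason, "flank-N")

  # without the N the same locus is kept
  s2 <- plant_run(2000L, "ATC", 8L, at = 900L)
  flt2 <- filter_candidates(ps, new_assembly_for_test(c(c1 = s2)), cfg)
  expect_equal(nrow(flt2$kept), 1L)
})

test_that("ranking is by max allele units and invariant to input order", {
  fx <- make_pipeline_fixture(seed = 44L)
  flt <- filter_candidates(fx$pstrs, fx$assembly, fx$cfg)
  kept <- flt$kept
  top <- rank_and_select(kept, top_k = 5L)
  expect_equal(nrow(top), min(5L, nrow(kept)))
  expect_true(all(diff(top$max_allele_units) <= 0))
  if (nrow(kept) > 5L) {
    rest <- kept[!paste(kept$contig, kept$start) %in% paste(top$contig, top$start), ]
    expect_true(min(top$max_allele_units) >= max(rest$max_allele_units))
  }
  # permutation invariance
  set.seed(45)
  for (i in 1:100) {
    shuffled <- kept[sample(nrow(kept)), , drop = FALSE]
    expect_equal(rank_and_select(shuffled, 5L)$locus_id, top$locus_id)
  }
  # small inputs pass through whole
  expect_equal(nrow(rank_and_select(kept[seq_len(min(3, nrow(kept))), ], 20L)),
               min(3L, nrow(kept)))
})

test_that("fragment-span arithmetic reproduces published marker ranges", {
  # internally consistent published rows: max = min + unit * (range width)
  expect_equal(expected_fragment_span(366, 3, 14, 18), 378)
  expect_equal(expected_fragment_span(345, 3, 6, 20), 387)
  expect_equal(expected_fragment_span(475, 3, 4, 10), 493)
  expect_equal(expected_fragment_span(305, 3, 5, 10), 320)
  expect_equal(expected_fragment_span(294, 3, 3, 9), 312)
  expect_equal(expected_fragment_span(255, 3, 5, 9), 267)
  # zero-range identity
  expect_equal(expected_fragment_span(123, 4, 7, 7), 123)
})

test_that("candidate FASTA records carry the locus in the title and flanks in the sequence", {
  fx <- make_pipeline_fixture(seed = 46L)
  flt <- filter_candidates(fx$pstrs, fx$assembly, fx$cfg)
  top <- rank_and_select(flt$kept, fx$cfg$top_k)
  out <- tempfile(fileext = ".fasta")
  write_candidate_fasta(top, out)
  back <- read_assembly(out)
  expect_equal(length(back$records), nrow(top))
  for (r in seq_len(nrow(top))) {
    title <- names(back$records)[r]
    parts <- strsplit(title, "|", fixed = TRUE)[[1L]]
    expect_equal(parts[1L], top$contig[r])
    expect_equal(parts[2L], sprintf("%d-%d", top$start[r] + 1L, top$end[r]))
    expect_equal(parts[3L], sprintf("%sx%d", top$motif[r], top$units[r]))
    expect_equal(parts[4L], sprintf("alleles=%d-%d", top$min_allele_units[r],
                                    top$max_allele_units[r]))
    seq <- back$records[[r]]
    expect_equal(nchar(seq), 600L + top$unit_size[r] * top$units[r])
    # re-scanning the emitted record recovers the repeat at offset 300
    rec <- find_strs(stats::setNames(seq, "rec"), fx$cfg)
    rec <- rec[rec$start == 300L, ]
    expect_equal(nrow(rec), 1L)
    expect_equal(rec$motif, top$motif[r])
    expect_equal(rec$units, top$units[r])
  }
})

test_that("the fixed FASTA holds exactly the fixed-in-some subset, even when empty", {
  fx <- make_pipeline_fixture(seed = 47L)
  flt <- filter_candidates(fx$pstrs, fx$assembly, fx$cfg)
  ranked <- rank_and_select(flt$kept, nrow(flt$kept))
  out <- tempfile(fileext = ".fasta")
  write_fixed_fasta(ranked, out)
  n_fixed <- sum(ranked$fixed_in_some)
  if (n_fixed > 0) {
    back <- read_assembly(out)
    expect_equal(length(back$records), n_fixed)
  }
  # no fixed candidates: a zero-record file
  none <- ranked[ranked$fixed_in_some == FALSE, , drop = FALSE]
  write_fixed_fasta(none, out)
  expect_equal(length(readLines(out)), 0L)
})
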