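test_that("SNP and indel records parse with QUAL and per-pool allele depths", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f,
    contig = c("c1", "c1"), pos = c(101L, 200L),
    ref = c("A", "A"), alt = c("T", "AATCATC"), qual = c(50, 99),
    samples = c("pool1", "pool2"),
    sample_fields = list(c("0/1:12,9:21", "0/0:20,0:20"),
                         c("0/1:10,5:15", "1/1:0,30:30"))
  )
  v <- parse_vcf(f)
  expect_equal(v$samples, c("pool1", "pool2"))
  expect_equal(v$variants$kind, c("SNP", "INDEL"))
  expect_equal(v$variants$qual, c(50, 99))
  expect_equal(v$variants$length_delta, c(0L, 6L))
  s1 <- v$support[v$support$var_id == 1L & v$support$sample == "pool1", ]
  expect_equal(c(s1$ref_count, s1$alt_count), c(12L, 9L))
})

test_that("multi-allelic records split into one variant per alternate with re-sliced AD", {
  set.seed(31)
  for (i in 1:50) {
    n_alt <- sample(2:3, 1)
    ref <- "A"
    alts <- unique(vapply(seq_len(n_alt), function(j) {
      paste0("A", strrep(sample(c("ATC", "GT", "C"), 1), sample(1:3, 1)))
    }, character(1)))
    ad <- sample(0:30, 1 + length(alts), replace = TRUE)
    f <- tempfile(fileext = ".vcf")
    write_test_vcf(f, contig = "c1", pos = 100L, ref = ref,
                   alt = paste(alts, collapse = ","), qual = 60,
                   samples = "p1",
                   sample_fields = list(sprintf("0/1:%s:%d", paste(ad, collapse = ","), sum(ad))))
    v <- parse_vcf(f)
    # independent hand-split: alt j pairs AD[1] with AD[1+j]
    expect_equal(nrow(v$variants), length(alts))
    expect_equal(v$variants$alt, alts)
    expect_equal(v$variants$length_delta, nchar(alts) - 1L)
    expect_true(all(v$variants$pos == 100L))
    for (j in seq_along(alts)) {
      sup <- v$support[v$support$var_id == v$variants$var_id[j], ]
      expect_equal(sup$ref_count, ad[1])
      expect_equal(sup$alt_count, ad[1 + j])
    }
  }
})

test_that("symbolic alternates are skipped with a warning; headerless files fail", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, contig = c("c1", "c1"), pos = c(10L, 20L),
                 ref = c("A", "A"), alt = c("<DEL>", "T"), qual = c(9, 9))
  expect_warning(v <- parse_vcf(f), "symbolic")
  expect_equal(nrow(v$variants), 1L)
  expect_equal(v$variants$alt, "T")

  writeLines(c("##fileformat=VCFv4.2", "c1\t1\t.\tA\tT\t5\t.\t."), f)
  expect_error(parse_vcf(f), "#CHROM")
})

test_that("missing QUAL parses as NA and GT-only support falls back with a warning", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1",
    "c1\t5\t.\tA\tAGG\t.\tPASS\t.\tGT\t0/1"
  ), f)
  expect_warning(v <- parse_vcf(f), "genotype")
  expect_true(is.na(v$variants$qual))
  sup <- v$support
  expect_equal(c(sup$ref_count, sup$alt_count), c(1L, 1L))
})

test_that("select_indels returns exactly the indel subset, order preserved", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf(f, contig = rep("c1", 5), pos = c(1, 5, 9, 13, 17) + 100L,
                 ref = c("A", "C", "G", "GTT", "T"),
                 alt = c("T", "CAT", "A", "G", "C"), qual = rep(50, 5))
  v <- parse_vcf(f)
  ind <- select_indels(v)
  expect_equal(ind$variants$kind, rep("INDEL", 2))
  expect_equal(ind$variants$pos, c(105L, 113L))
  empty <- select_indels(parse_vcf(write_test_vcf(
    tempfile(fileext = ".vcf"), contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), qual = numeric(0)
  )))
  expect_equal(nrow(empty$variants), 0L)
})

test_that("left-normalization is semantics-preserving, leftmost and idempotent", {
  set.seed(32)
  # build a contig with a run and express the same deletion several ways
  s <- plant_run(600L, "ATC", 10L, at = 200L)
  a <- new_assembly_for_test(c(c1 = s))
  # deletion of one unit placed mid-run (1-based pos 210, REF CATC -> C)
  raw <- list(pos = 210L, ref = substr(s, 210, 213), alt = substr(s, 210, 210))
  nz <- normalize_indel("c1", raw$pos, raw$ref, raw$alt, a)
  expect_lt(nz$pos, raw$pos)
  expect_equal(nz$pos, 200L)  # anchored one base before the run
  # semantic equivalence: both representations edit to the same sequence
  expect_identical(apply_variant(s, raw$pos, raw$ref, raw$alt),
                   apply_variant(s, nz$pos, nz$ref, nz$alt))
  # idempotence
  nz2 <- normalize_indel("c1", nz$pos, nz$ref, nz$alt, a)
  expect_identical(nz, nz2)
  # random representations of random unit deletions across the run
  for (i in 1:25) {
    d <- sample(1:3, 1) * 3L
    p <- sample(201:(230 - d), 1)
    raw <- list(pos = p, ref = substr(s, p, p + d), alt = substr(s, p, p))
    nz <- normalize_indel("c1", raw$pos, raw$ref, raw$alt, a)
    expect_identical(apply_variant(s, raw$pos, raw$ref, raw$alt),
                     apply_variant(s, nz$pos, nz$ref, nz$alt))
    expect_identical(normalize_indel("c1", nz$pos, nz$ref, nz$alt, a), nz)
  }
  expect_error(normalize_indel("c1", 210L, "A", "T", a), "indel")
  expect_error(normalize_indel("c1", 210L, "TTTT", "T", a), "mismatch")
})

test_that("write/parse round trip is loss-free for core fields", {
  set.seed(33)
  f <- tempfile(fileext = ".vcf")
  n <- 20L
  pos <- sort(sample(100:5000, n))
  ref <- sample(c("A", "C", "GATC"), n, replace = TRUE)
  alt <- ifelse(nchar(ref) > 1, substr(ref, 1, 1), paste0(ref, "TG"))
  qual <- round(runif(n, 10, 99), 1)
  fields1 <- sprintf("0/1:%d,%d:%d", sample(5:30, n, TRUE), sample(5:30, n, TRUE), 40L)
  write_test_vcf(f, contig = rep("c1", n), pos = pos, ref = ref, alt = alt,
                 qual = qual, samples = "p1", sample_fields = list(fields1))
  v <- parse_vcf(f)
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(v, f2)
  v2 <- parse_vcf(f2)
  expect_equal(v2$variants[, c("contig", "pos", "ref", "alt", "qual", "kind")],
               v$variants[, c("contig", "pos", "ref", "alt", "qual", "kind")])
  expect_equal(v2$support[, c("sample", "gt", "ref_count", "alt_count")],
               v$support[, c("sample", "gt", "ref_count", "alt_count")])
})

test_that("parsing agrees with vcfR on a simulated dataset", {
  sim <- simulate_dataset(out_dir = file.path(tempdir(), "vcfr_sim"), seed = 34,
                          n_contigs = 2L, contig_len = 9000L,
                          n_poly = 4L, n_fixed = 2L, n_mono = 1L,
                          n_trap_nonmult = 1L, n_trap_lowqual = 1L,
                          n_trap_flankn = 1L)
  mine <- parse_vcf(sim$paths$vcf)
  ref <- vcfR::read.vcfR(sim$paths$vcf, verbose = FALSE)
  fix <- as.data.frame(ref@fix, stringsAsFactors = FALSE)
  # expand multi-allelic rows of the reference parser by hand
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  exp_keys <- unlist(lapply(seq_len(nrow(fix)), function(i) {
    paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alt_list[[i]], sep = "|")
  }))
  got_keys <- paste(mine$variants$contig, mine$variants$pos,
                    mine$variants$ref, mine$variants$alt, sep = "|")
  expect_setequal(got_keys, exp_keys)
  expect_equal(sort(colnames(ref@gt)[-1]), sort(mine$samples))
})
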