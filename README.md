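# strscreen

Discovery of **polymorphic microsatellite (STR/SSR) markers** from a draft
assembly and the variant calls of barcoded population sequencing pools.

Classical STR-marker development scans assembled sequence for tandem repeats
and hands the investigator thousands of candidates of unknown value: whether a
locus is actually polymorphic in the study populations is only learned later,
at the PCR bench, where most candidates fail. When each population is
sequenced as its own barcoded (indexed) pool and the reads are mapped back to
the assembly, the variant calls already contain the answer. An indel inside a
repeat run whose length is a whole number of repeat units is direct evidence
that the locus segregates for different repeat counts — and the per-pool
allele depths say whether the variation lies within a population, between
populations, or is fixed in one of them.

`strscreen` implements this screen end to end:

* scan contigs for **maximal perfect tandem repeats** of unit size 2–5 bp
  with ≥ 5 complete units (motif primitive, no `N`, each physical run
  reported once);
* parse the VCF, split multi-allelic records, keep indels, **left-normalize**
  them against the assembly, and assign each to the repeat locus containing
  its edit interval; the repeat counts of the alternate alleles are
  `units + Δ/unit_size`;
* classify each locus per population pool from pooled allele fractions
  `f = alt/(ref+alt)`: `fixed_ref` (f ≤ 0.05), `fixed_alt` (f ≥ 0.95),
  `polymorphic`, or `no_data` below the depth gate; flag loci **fixed in one
  population** while variable elsewhere;
* apply the candidate filters in order — motif size (default tri-nucleotide
  only), variant quality, N-free complete 300 bp flanks, unit-consistency —
  rank by the largest implied repeat count, select the top 20, and write
  **primer-ready FASTA** (`left flank + repeat + right flank`) plus a
  separate fixed-list FASTA and a full TSV report;
* a **simulator** fabricates genomes with planted repeats and matched
  two-pool VCFs with an exact truth table, so the whole pipeline is testable
  offline.

Expected PCR fragment sizes follow the standard arithmetic
`max_len = min_len + unit_size × (max_units − min_units)`
(`expected_fragment_span()`), letting observed allele ranges be checked
against the repeat counts implied by the calls.

## Worked example

Simulate a small two-pool dataset and run the screen (the same works with any
real assembly + VCF):

```r
library(strscreen)

sim <- simulate_dataset(out_dir = "demo", seed = 1,
                        n_contigs = 2, contig_len = 12000,
                        n_poly = 6, n_fixed = 2, n_mono = 2,
                        n_trap_nonmult = 1, n_trap_lowqual = 1, n_trap_flankn = 1)
res <- discover_markers(sim$paths$fasta, sim$paths$vcf,
                        out = "demo/candidates.fasta",
                        fixed_out = "demo/fixed.fasta")

res$summary[c("n_loci", "n_indels", "n_kept", "n_candidates", "n_fixed")]
#> $n_loci        [1] 13     repeats found in the assembly
#> $n_indels      [1] 24     indel records in the VCF (after splitting)
#> $n_kept        [1] 8      loci passing all candidate filters
#> $n_candidates  [1] 8      top-k selection (k = 20 > 8 here)
#> $n_fixed       [1] 2      candidates fixed in one pool, variable in the other

res$candidates[1:2, c("contig", "start", "motif", "units",
                      "min_allele_units", "max_allele_units", "fixed_in_some")]
#>   contig start motif units min_allele_units max_allele_units fixed_in_some
#> 1  ctg02  6925   GTA    20               19               20          TRUE
#> 2  ctg02  3162   CAA    19               17               19         FALSE

table(res$excluded$exclusion_reason)
#>           flank-N          low-qual non-unit-multiple
#>                 1                 1                 1
```

The first candidate is a `GTA` repeat of 20 units at ctg02:6926–6985 (1-based)
whose indel evidence implies alleles of 19 and 20 units; pool A is fixed for
the longer allele while pool B is polymorphic, so it also appears in the fixed
list. Its FASTA record is ready for primer design — the repeat starts at
offset 300 in every record:

```
>ctg02|6926-6985|GTAx20|alleles=19-20|pops=popA:fixed_alt,popB:polymorphic
CCGATATGGT...GTAGTAGTA...ACCGGTT   (300 bp flank + repeat + 300 bp flank)
```

The same pipeline is available from the shell via the installed script
(`exec/strscreen`):

```sh
strscreen simulate --out-dir demo --seed 1
strscreen discover --fasta demo/ref.fa --vcf demo/calls.vcf \
    --out demo/candidates.fasta --fixed-out demo/fixed.fasta \
    --report demo/report.tsv --summary-json demo/run.json
strscreen scan --fasta demo/ref.fa --bed demo/loci.bed --summary demo/counts.tsv
```

## Documentation

The methods vignette (`vignettes/marker-screening.Rmd`) describes the model
and its assumptions, every tunable threshold with its default and rationale,
what the simulator does and does not emulate, and known limitations.
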