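---
title: "Screening assemblies and pooled-library variant calls for polymorphic STR markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening assemblies and pooled-library variant calls for polymorphic STR markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strscreen)
```

## The problem

Short tandem repeats (STRs, microsatellites) are the workhorse codominant
markers of population genetics. Conventional marker development finds
thousands of repeats in assembled sequence and leaves the expensive question —
*is this locus actually polymorphic in my populations?* — to wet-lab PCR
screening, where historically only a small fraction of candidates survive.

`strscreen` implements the alternative screening strategy: sequence each
study population as its own barcoded (indexed) pool, map the reads back to a
draft assembly, call variants, and then intersect the *indel* calls with the
repeat loci. An indel whose length is a whole number of repeat units, sitting
inside a repeat run, is direct in-silico evidence that the locus segregates
for different repeat counts — before a single primer is ordered. Because the
pools are barcoded per population, the same allele depths also say *where*
the variation lies: within a population, between populations, or fixed in one
of them.

## The pipeline

Given an assembly and a VCF with one sample column per population pool:

1. **Repeat scan.** Every contig is scanned for maximal perfect tandem
   repeats with unit sizes 2–5 bp and at least `min_units` (default 5)
   complete copies.
2. **Indel intersection.** VCF records are split per alternate allele,
   non-indels are dropped, indels are left-normalized against the assembly,
   and each indel is assigned to the repeat locus whose interval
   `[start − unit_size, end)` contains its edit interval. Each indel's length
   change, divided by the unit size, converts the reference repeat count into
   the repeat counts of the alternate alleles.
3. **Population status.** Per pool, the alternate-allele fraction
   `f = alt/(ref + alt)` from the AD field classifies the locus as
   `fixed_ref` (`f ≤ 0.05`), `fixed_alt` (`f ≥ 0.95`), `polymorphic`
   (otherwise) or `no_data` (informative depth below `min_depth`). A locus is
   *fixed in some population* when one pool is fixed while another is
   polymorphic or fixed for a different allele — the most useful loci for
   distinguishing populations.
4. **Candidate filters**, in a fixed order that defines the single reported
   exclusion reason:
   a. *motif-size* — only configured unit sizes pass (default tri-nucleotide,
      because di-nucleotide markers are notoriously hard to score due to PCR
      stutter);
   b. *low-qual* — every supporting record needs `QUAL ≥ qual_min`;
   c. *flank-N* — both 300 bp flanks must be complete and free of `N` calls,
      so primers can be designed anywhere in the flank;
   d. *non-unit-multiple* — all length changes must be whole repeat units
      (anything else suggests the variation is not simple repeat-count
      variation; such markers also fail wet-lab scoring).
5. **Ranking and output.** Candidates are ranked by the largest implied
   repeat count of any allele, the top `top_k` (default 20) are written as
   primer-ready FASTA records (`left flank + repeat + right flank`, repeat
   offset exactly `flank_len`), and the fixed-in-some-population subset of
   *all* kept candidates goes to a second FASTA.

```{r example}
sim <- simulate_dataset(out_dir = tempdir(), seed = 1,
                        n_contigs = 2, contig_len = 12000,
                        n_poly = 6, n_fixed = 2, n_mono = 2,
                        n_trap_nonmult = 1, n_trap_lowqual = 1, n_trap_flankn = 1)
res <- discover_markers(sim$paths$fasta, sim$paths$vcf)
res$summary[c("n_loci", "n_indels", "n_kept", "n_candidates", "n_fixed")]
head(res$candidates[, c("contig", "start", "motif", "units",
                        "min_allele_units", "max_allele_units", "fixed_in_some")])
```

## What exactly is a repeat locus

A locus is one *maximal periodic region*: an interval that cannot be extended
by a single base on either side while keeping its period, whose repeat unit
(the first `unit_size` bases — the phase observed at the region start) is
*primitive* (not itself a repetition of a shorter unit), containing no `N`,
and covering at least `min_units` complete units. The reported interval ends
after the last complete unit; a trailing partial unit still blocks rightward
extension but is not part of the locus. These choices mean each physical run
is reported exactly once, at its primitive unit size: `ATATATAT…` is a run of
`AT`, never of `ATAT`, and homopolymers are never reported (unit sizes start
at 2). Overlapping runs of *different* unit sizes are all kept; when an indel
could be assigned to more than one, the locus whose unit size divides the
indel length wins, with remaining ties going to the longer locus, then the
smaller start.

Two conventions are deliberate and configurable:

* **Inclusive minimum of 5 units.** The screening protocol that motivated the
  package describes repeats "greater than five repeat units" in prose but
  tabulates discovery counts beginning at a 5-repeat row; we follow the
  tables, default to `min_units = 5` *inclusive*, and expose `--min-units`.
* **No reverse-complement folding.** `canonical_motif()` folds rotations only
  (`TCA`, `CAT` → `ATC`), so `ATC` and `GAT` stay distinct classes, matching
  how published marker tables report motifs on the reference strand;
  `rc_canonical = TRUE` folds strands for users who prefer strand-free
  classes. The displayed motif is always the phase at the locus start.

Only *perfect* repeats are detected. Scanners that admit mismatches or
interruptions (imperfect repeats) find more loci, but an indel's repeat-count
interpretation is only exact for perfect runs, and published marker motifs
for this protocol are perfect.

## Input dialects and coordinates

Assemblies are accepted in standard FASTA (any line wrap) or a tab-delimited
dialect (one line per record: `name<TAB>sequence`), plain or gzipped, with
`--dialect auto` sniffing the first character. Lowercase (soft-masked) bases
are uppercased rather than treated as `N` — masking provenance in draft
assemblies is unreliable. IUPAC ambiguity codes other than `N` are rejected
outright, because every downstream filter reasons only about `N`. In the tab
dialect everything before the first tab is the name.

Internally all coordinates are 0-based half-open (VCF positions are converted
on input); FASTA titles, BED names and reports present 1-based inclusive
coordinates.

The whole-genome, single-strand mode (`concat_with_spacer()`, `--concat`)
joins all contigs with 100 `N` bases between neighbours and keeps a
coordinate map. The spacer must be at least `max(unit_sizes) × min_units`
(25 bp by default) so that no reportable repeat can bridge a junction; since
`N` breaks every run, scanning the joined strand is provably equivalent to
scanning per contig, and the test suite checks this equivalence on simulated
assemblies.

## Pooled fixation calls, not genotypes

A pool of dozens of individuals cannot be genotyped as a diploid, so
"fixed" must be defined on pooled allele fractions. We use the maximum
per-variant alternate fraction across a locus's assigned indels (the most
permissive evidence of polymorphism), thresholds 0.05/0.95, and an
informative-depth gate of 8 reads (`ref + alt` supporting reads, letting
other alleles absorb depth). All three are configurable; the defaults
tolerate about one miscalled read in twenty while still calling fixation
decisively at typical pool depths (~30×). When a VCF lacks AD, support falls
back to genotype-call allele counts with a warning — such pseudo-counts
rarely reach `min_depth`, so GT-only files should be analysed with
`min_depth = 0` and the fixation calls treated with caution. Missing QUAL
(`.`) fails any positive quality threshold rather than passing silently.

## What the simulator emulates — and what it does not

`simulate_dataset()` builds the fixture every claim in this package is tested
against: i.i.d. random contigs *scrubbed by rejection* of any accidental
reportable repeat, planted loci with pinned boundary bases (so each run is
maximal exactly as planned), and a fabricated two-pool VCF whose indels are
written pre-left-normalized with `AD` counts equal to `round(depth × f)` for
the planted fraction `f`. Depths are Poisson around `depth_mean = 30` with a
floor of 12, so rounding can never move a planted fraction across the
0.05/0.95 thresholds: the expected verdict of every locus is computable from
the plan alone, making the truth table exact. Planted types cover
polymorphic loci (intermediate fractions 0.25–0.75 in both pools, one or two
alleles), fixed loci (fractions 1.0 and 0.3), monomorphic loci (no indel),
and one trap per candidate filter. Decoy SNPs and off-locus indels exercise
the record filters, and two-allele insertion loci are emitted as single
multi-allelic records half the time to exercise allele splitting.

The simulator deliberately does *not* model reads: no sequencing error, no
mapping ambiguity, no stutter noise in allele depths, no imperfect repeats,
no genome-scale repeat families. Green tests therefore demonstrate that the
*intersection, classification, filtering and output machinery* is exact, not
that any particular variant caller is reliable at STRs on real reads —
upstream mapping and calling quality remains the user's responsibility.

## Numerical and degenerate-input choices

* Scanning uses byte-level comparison vectors per unit size; ties and output
  order are fixed by radix sorting on (contig, start, unit size), so results
  are locale-independent and runs are byte-deterministic.
* Ranking order is total — max allele units, then reference units, then
  (contig, start) — so the top-k set is invariant to input permutation.
* An indel anchored one base left of a run (the left-normalized convention)
  is still assigned: the assignment window starts `unit_size` bases left of
  the locus.
* Deletions larger than the remaining run, or any non-unit-multiple length
  change, mark the locus unit-inconsistent rather than producing a negative
  repeat count.
* Flank truncation at contig ends is reported via a completeness flag (and
  fails the flank filter), never as an error; a flank that reaches into a
  concatenation spacer fails the same `N` rule with no special casing.
* Empty inputs (no loci, no indels, no candidates) produce empty but valid
  outputs, including a zero-record fixed FASTA.

## Problem sizes used in the checks

The bundled validation runs at desk scale, chosen to exercise every code path
while keeping the whole suite fast: scanner-versus-oracle equivalence on
hundreds of random 2 kb sequences across GC 0.3–0.7, and end-to-end recovery
on a simulated 200 kb genome (4 × 50 kb contigs) carrying 60 planted loci —
40 with unit-multiple indels (10 of them fixed in one pool), 10 monomorphic,
and 10 filter traps. Full-genome screens of real assemblies are simply more
contigs; time scales linearly in assembly length and VCF size.

## Known limitations

* Perfect repeats only; compound and interrupted repeats are out of scope.
* Fixation calls are threshold heuristics on pooled fractions, not
  genotype-likelihood inference; downstream statistics (heterozygosity, HWE,
  linkage) belong to dedicated population-genetics software once individuals
  are genotyped.
* Primer design itself is delegated: the FASTA output is shaped for direct
  use in Primer3-class tools.
* The original interactive prompt-driven workflow is replaced by flags plus
  an equivalent YAML config (flags win); there is no prompting mode.
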