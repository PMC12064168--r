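---
title: "Comparative tandem repeat analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative tandem repeat analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trcompare)
```

This vignette documents the models and procedures implemented by
`trcompare`, the parameters that matter and why their defaults are what they
are, what the synthetic fixtures establish (and what they cannot), and the
design choices made where the problem was genuinely open.

## 1. The problem

A tandem repeat (TR) is a locus where a motif is repeated head-to-tail. Two
assemblies each come with a TR catalog (typically from Tandem Repeat
Finder); the comparative question is which loci in catalog A and catalog B
are *the same locus*, so that downstream analyses (length divergence,
per-population variation) operate on homologous pairs. `trcompare` answers
it in three stages: catalog cleaning, coordinate lifting, and reciprocal
homology gating; a fourth stage summarizes within-species genotype VCFs.

## 2. Catalog cleaning

TRF reports 1-based inclusive coordinates; the package converts to 0-based
half-open (BED) at ingest and never again. Overlapping records — TRF often
reports several decompositions of one array — are merged into their union
span. The merge must pick one representative for the non-coordinate
attributes; we keep the member with the highest alignment score, tie-broken
by smaller start and then lexicographically smallest motif, purely for
determinism. The merged record's `sequence` is dropped (set to `NA`) when
more than one member contributed, because the representative's array no
longer spans the union. Abutting intervals are *not* merged: under half-open
semantics overlap requires `start2 < end1`, and touching records share no
base.

Filtering keeps records with total length ≤ 10 kbp **and** copy number
≥ 2.5. Both bounds are deliberately strict readings ("exceeding",
"< 2.5"): a record of exactly 10000 bp or exactly 2.5 copies survives. The
filter is idempotent and order-preserving.

Under the default TRF scoring (match weight 2, minimum reported alignment
score 24) a perfect array scores `2 × length`, so the shortest array that
can appear in a default catalog is `ceiling(24 / 2) = 12` bp.
`trf_min_length()` computes the bound; the acceptance machinery verifies it
against generated catalogs. The TRF defaults themselves
(`trf_defaults()`) are provenance metadata only — running TR detection is
out of scope.

## 3. The liftover engine

Chains describe a pairwise assembly alignment as scored lists of ungapped
blocks separated by target-side (`dt`) and query-side (`dq`) gaps. Parsing
is eagerly validated: block sizes plus gaps must sum exactly to the header
spans on both sides, and an inconsistent chain aborts the run naming its id
— silently skipping a corrupt chain would bias every downstream comparison.

`lift_interval()` mirrors `liftOver` semantics:

* only the **single best-scoring** chain overlapping the interval is used
  (ties broken by chain id); there is no multi-chain stitching;
* the mapped fraction is the share of source bases inside aligned blocks;
  a result is emitted only when it reaches `min_match`;
* the emitted query span bridges from the first to the last mapped base
  (span semantics), because TR loci are compared downstream as whole
  intervals, not as piecewise fragments;
* all emitted coordinates are plus-strand 0-based half-open; on a
  minus-strand chain each strand-local base `p` maps to
  `q_size − p − 1`.

`min_match` defaults to 0.95, the conventional liftOver default; the
cross-species homology search may justify lowering it. Unmapped intervals
carry a reason: `no_chain` when nothing overlaps, `partially_deleted` when
the single relevant chain aligns too few bases, and `split_across_chains`
when several chains touch the interval but the best one alone fails
`min_match` — the three cases need different biological interpretations
(absence, deletion, rearrangement/assembly break).

Correctness is established against an independent oracle: a per-base mapper
that walks every block for every base. The unit and acceptance suites
compare spans, fractions and strands over hundreds of random chains (mixed
strands, up to 6 blocks) and verify A→B→A round trips through exact inverse
chains.

## 4. Reciprocal homology

For each direction, the lifted catalog is intersected with the other
assembly's catalog. The overlap fraction is measured **relative to the
lifted interval** (like `bedtools intersect -f` on the lifted file); the
threshold's denominator is genuinely ambiguous in the field, so the choice
is documented and a `reciprocal = TRUE` mode additionally requires the
fraction relative to the catalog record. One lifted locus may pair with
several catalog records; no best-hit collapse happens by default (an
opt-in `best_hit` flag keeps the highest-similarity match).

Candidate pairs are then gated on motif similarity from a Needleman–Wunsch
global alignment with linear gap penalties. The paper trail for such tools
rarely states scoring parameters; we default to the simplest standard
scheme (+1 match, −1 mismatch, −2 gap), fully configurable. Percent
similarity is `100 × matched columns / alignment columns`, with gap columns
counted in the denominator — denominators differ across tools, so this is
stated explicitly. Identity is computed from one deterministic traceback
(diagonal > up > left on ties); the test oracle checks the *score* by
exhaustive enumeration of all global alignments, not the identity, since
co-optimal alignments can differ in identity.

Motifs are compared as reported (`plain` mode) by default. Because a motif
is only defined up to cyclic rotation and strand, an opt-in
`best_rotation_revcomp` mode takes the maximum plain identity over all
rotations of the second motif and of its reverse complement. Rotation mode
is not exactly symmetric in its arguments, which is one reason similarity
is recomputed independently in each direction; the reported `similarity`
column is the A→B value.

The final phTR set is the intersection of the two directional candidate
sets, matched on the (locus A, locus B) identity pair — the strictest
reading of "intersected". Matching by identity (rather than by coordinate
overlap of the two directional tables) cannot create pairs that either
direction rejected.

## 5. Population-genetic summaries

`parse_tr_vcf()` delegates VCF parsing to `VariantAnnotation::readVcf` and
resolves allele sequences from GT indices against REF/ALT. Alleles are
identified by their **full sequence string**, not their length, because TR
genotypers that report sequence composition reveal same-length alleles that
differ in composition; a `by = "length"` mode collapses them. Phasing is
ignored; haploid or higher-ploidy genotypes are an error (the workflow
targets diploid genotyper output); missing genotypes are excluded from
every denominator.

Per locus with `n` called samples and allele frequencies `p_i` over the
`2n` called chromosomes:

* observed heterozygosity `Ho = (# samples with two distinct alleles) / n`;
* gene diversity `He = (2n / (2n − 1)) (1 − Σ p_i²)` — Nei's unbiased
  estimator. The source workflow names the statistic but not the formula;
  the unbiased form is the field's standard for modest cohort sizes, and
  `unbiased = FALSE` drops the correction;
* the number of unique alleles and the allele-length range.

`population_summary()` recomputes everything within each population, so a
Wahlund-style configuration (two populations fixed for different alleles)
correctly shows `Ho = 0` in both populations while the pooled gene
diversity is positive.

## 6. The synthetic world

`fixture_spec()` states a toy world once; everything flows from its seed and
the same spec is byte-identical on re-run. Genome A is i.i.d. uniform
background with planted TR arrays (non-overlapping, ≥ 50 bp spacing, all
passing the default filters). Genome B is *derived* from A: shared TRs keep
their array length but carry substituted motifs; private TRs are backed by
plain background in the other genome; unaligned blocks are inserted into
one genome or the other. Because the chain files are derived from the same
edit plan, they are exact by construction and pass full parse-time
validation — the fixtures test the pipeline, never the other way around.

Defaults: 2 chromosomes × 60 kb, 50 shared + 20 private TRs per species,
motifs 10–30 bp, 3–8 copies, 5% motif divergence, 4 unaligned blocks of
200–800 bp, 24 samples in 3 populations, 1–4 alleles per locus. Sizes are
desk-scale stand-ins for chromosome-level assemblies; divergence and
copy-number ranges are in the range reported for primate TR comparisons.

Two generator choices deserve justification:

* **Divergence is exact, not sampled.** A shared motif of length `L`
  receives exactly `floor(rate × L)` substitutions at distinct positions.
  The spec of the world calls the rate an expectation, but recovery
  guarantees ("all planted pairs found at thresholds looser than the
  planted divergence") are only provable when realized divergence is
  *bounded* by the rate: under i.i.d. substitution a 10-bp motif has a
  ~9% chance of exceeding a 5% rate at least twofold. The floor
  construction gives planted similarity the closed form
  `100 × (1 − k/L) ≥ 100 × (1 − rate)`. The cost is a downward bias in
  realized divergence for short motifs (a 10-bp motif at 5% gets 0
  substitutions), which is why the default motif range extends to 30 bp.
* **Substitutions only, no motif indels**, so homologous arrays have equal
  lengths, lifted intervals coincide exactly with catalog records, and the
  overlap stage is exercised with known-true fractions of 1. Length
  variation between *alleles* is generated separately in the cohort module.

What a green fixture test does **not** establish: recovery under
alignment noise (fixture chains are exact, real chains are not), motif
indel divergence, nested or interrupted repeats, reference bias in
genotyping, or anything about performance at the scale of millions of
catalog records.

The cohort generator draws per-population allele frequencies from a flat
Dirichlet and diploid genotypes i.i.d. from them (random union of gametes,
i.e. within-population Hardy–Weinberg), records the truth, and emits the
VCF with full allele sequences and an `AL` length field. Its seed is
`spec$seed + 1` so the cohort is reproducible whether or not the genome
pair was generated first.

## 7. Numerical and degenerate-input choices

* Empty catalogs, empty chain overlap, all-missing loci: every operation
  returns typed empty results or `NA` statistics rather than erroring,
  except where the input itself is malformed (those error naming the line
  or record).
* NW traceback ties are fixed (diagonal > up > left); merge ties are fixed
  (score, start, motif); CLI and file outputs are deterministic given a
  seed.
* Coordinates are integers throughout; overlap fractions and similarities
  are exact ratios of integers, so threshold comparisons (`>=`) are safe
  without epsilon tolerances.
* Gene diversity uses `2n/(2n − 1)` which is defined for `n ≥ 1`; a locus
  with a single called sample yields `He ∈ {0, 1}` and is reported as such
  rather than suppressed.

## 8. Known limitations

* Homology is pairwise only; no multi-species graphs, no
  orthology/paralogy disambiguation, no synteny filtering.
* Motifs, not full repeat arrays, are aligned; two loci with similar motifs
  but unrelated array structure can pass the gate.
* The liftover engine does not stitch chains; loci spanning chain breaks
  are reported unmapped rather than partially mapped.
* Statistics stop at `Ho`/`He`, allele counts and length ranges — no
  F-statistics, HWE tests, or mutation-model inference.
* The pure-R Needleman–Wunsch is sized for motifs (typically ≤ 2 kb periods,
  usually ≤ 100 bp); aligning full arrays with it would be slow.
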