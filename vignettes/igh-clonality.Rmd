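---
title: "Detecting V(D)J recombination and its genotyping footprint in LCL short-read data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting V(D)J recombination and its genotyping footprint in LCL short-read data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igclone)
```

## The problem

Lymphoblastoid cell lines (LCLs) are EBV-immortalized B cells, and B cells
carry somatic V(D)J rearrangements: in each developing cell one IGHV, one
IGHD and one IGHJ gene segment are joined and the intervening DNA — up to
hundreds of kilobases of the immunoglobulin heavy-chain (IGH) locus on
chr14 — is excised. DNA sequenced from an LCL therefore does not represent
the donor's germline over IGH. If the line is dominated by a single clone,
one haplotype is missing a large interval entirely, and genotype callers
that assume two chromosomes will call heterozygous positions homozygous,
miss variants, and mistake somatic hypermutation (SHM) for germline
heterozygosity. Those per-sample errors propagate into population
resources: allele-frequency panels and linkage-disequilibrium (LD) maps
built from LCL cohorts are distorted over IGH.

`igclone` implements the short-read analysis of this phenomenon:

1. **Signatures** of V(D)J deletions in paired-end alignments — enrichment
   of large insert sizes (a fragment spanning an excised interval maps with
   insert = fragment length + deletion size), depleted read depth over the
   excised region, and direct *junction read pairs* with one mate on an
   IGHJ segment and the other on an IGHV segment.
2. **Clone profiling**: junction pairs grouped by (IGHJ, IGHV) identity;
   each unique pair is a clone, its read support over the total is its
   frequency, and the top pair defines the dominant clone and the interval
   reported as the sample's somatic deletion
   `[J.end, V.start)` — the excised span between the joined segments.
3. **Genotype impact**: per-sample heterozygosity partitioned at the 3'
   end of the dominant recombined V segment (its reference *start* — IGH
   is minus-strand), compared centromeric vs telomeric with a paired
   Wilcoxon test; SHM surfacing as excess heterozygous calls inside the
   recombined V segment, correlated with clonality.
4. **Population impact**: samples binned into dominance strata
   ((0,25], (25,50], (50,75], (75,100] percent of junction reads from the
   top clone); allele frequencies and haplotype r² compared between the
   extreme strata.

Because the real cohorts behind this analysis are terabyte-scale, the
package ships a seeded simulator that reproduces the data-generating
process at desk scale, and every claim the package makes is tested against
it.

## The simulator

A simulated sample is a pool of `n_clones` B-cell clones with fractions
that either follow a symmetric Dirichlet (`dirichlet_alpha`, default 1) or
give the top clone an explicit `dominant_fraction` with the remainder
split evenly. Per clone:

* the expressed haplotype (hap 1) joins one IGHJ and one IGHV segment,
  drawn uniformly, deleting `[J.end, V.start)`;
* the second haplotype follows `second_allele_mode`: the default
  `dj_only` gives it a D–J join confined to the D region (both chromosomes
  of a B cell undergo D–J joining; usually only one completes V–DJ), and
  `full_vdj` draws an independent V–DJ join — the harsher case;
* SHM positions are placed uniformly in the recombined V segment at
  `shm_rate` (default 5×10⁻³/bp, an antigen-experienced magnitude), on the
  expressed haplotype only. Junction microdiversity (N/P nucleotides) is
  not modelled.

Germline variation is uniform-density biallelic SNPs (`snp_density`,
default 1/1000 bp — a common-variant panel density, not full site
spectra), population frequencies Beta-distributed (default uniform), and
per-sample phased genotypes drawn under Hardy–Weinberg.

Reads are paired 150 bp with Normal(450, 50) fragment lengths truncated to
`[300, 600]` bp at 30× coverage — a PCR-free short-read library. Fragments
are sampled uniformly along each clone-haplotype's *post-deletion*
template in proportion to clone fraction, so depth over a region equals
coverage times the fraction of templates retaining it; a fragment spanning
a junction maps back to reference coordinates with the deletion size added
to its insert. A read that itself straddles the junction is emitted
*clipped to its larger mapped side*, exactly as an aligner soft-clips
junction reads; stubs under `min_clip = 30` bp (a typical seed length) are
dropped. Emitting the clipped records matters: they carry a substantial
share of the junction evidence, and without them a 30× library yields only
2–3 junction pairs per sample, too few to profile clones at all. No base
sequences, quality strings or sequencing errors are modelled — the
detector consumes only coordinates, flags and insert sizes.

The upper fragment truncation at mean + 3 sd interacts with the bundled
annotation: with J segments spaced ≥ ~560 bp apart, no fragment can anchor
one read on a *non-selected* J segment and still reach across the junction
into the V segment, so a monoclonal simulation can never emit a spurious
second (J, V) event. The bundled annotation
(`igh_segments_synthetic.bed`) is synthetic but hg38-plausible: 6 J, 27 D
and 50 V segments inside the published IGH span, with IGHJ1 ending at the
published D-region start and IGHV6-1 starting at the published V-region
boundary; its J spacing is wider than the real cluster's precisely to keep
junction attribution unambiguous at 150 bp reads. Real analyses should
supply their own BED.

Genotype calls are emulated directly from the simulated reads: per SNP,
covering reads contribute the germline allele of their originating
haplotype (or the SHM allele), and the call is missing at depth 0,
heterozygous when the minor-allele read fraction reaches `het_threshold`
(0.2) at depth ≥ `min_depth` (4), else homozygous for the majority allele
— deliberately the simplest threshold caller; it reproduces the
het-to-hom failure mode without modelling genotype likelihoods.

## What read support the library geometry allows

A junction read pair needs one mate over a ~50 bp J segment and its mate
across the junction in the ~450 bp V gene body. With fragment starts at
coverage/(4·read length) ≈ 0.05 per bp per haplotype and an effective
anchor window of ~170 bp, the expectation is ~7 junction pairs per sample
at 30× — the same order as real cohorts report (tens of pairs). Two
consequences, verified in the test suite:

* the *share* of junction reads carrying a given clone's (J, V) identity
  is an unbiased estimate of its fraction (tested as a pooled share over
  24 simulation streams), but the *maximum*-share estimator that defines
  the dominant clone is order-statistic biased upward by ~+0.08 at this
  support, and single-sample estimates carry sd ≈ √(f(1−f)/7);
* per-sample dominant-fraction recovery therefore correlates with truth at
  r ≈ 0.85–0.92 across a 0.1–1.0 grid — read support, not the detector,
  is the limiting factor. Monoclonal samples are nevertheless recovered
  exactly (one clone, the true pair), because the annotation geometry
  forbids false events.

Two further facts about the generative process are worth stating because
they bound what any detector can see. The number of junction-spanning
fragments is proportional to the *sum* of clone fractions — one junction
per haplotype regardless of how clonality is distributed — so the
large-insert fraction separates recombined samples from unrecombined
controls sharply but is flat across dominance levels. Likewise D-region
depth is depleted in *every* sample (both chromosomes lose D–J intervening
DNA in every clone), so it is a recombination signature, not a clonality
gradient; the quantity that does grow with dominance is the depth deficit
over the dominant clone's own excised interval.

## Numerical and design choices

* **Coordinates.** All intervals are 0-based half-open (BED); VCF
  positions are 1-based and converted at the boundary. A 1-based position
  p overlaps `[start, end)` iff `start < p ≤ end`.
* **Deletion anchor.** Distance from the J segment's end to the V
  segment's start — the excised span; reproduces the published 74.3 Kb
  minimum from the published region boundaries.
* **Mate–segment overlap.** ≥ 1 bp with the segment body, no padding; a
  mate overlapping several segments of one family takes the larger
  overlap, ties alphabetically. Dominant-event ties take the larger
  deletion (the more conservative masked region), then lexicographic
  (J, V). Secondary and duplicate records are excluded; `min_mapq`
  defaults to 0.
* **Undetermined ≠ monoclonal.** Zero junction reads yield an
  `undetermined` profile, excluded from strata with a logged count.
* **Breakpoint convention.** The heterozygosity partition splits at the
  dominant V segment's reference start + 1 (1-based), telomeric side
  inclusive; sites with missing genotypes are excluded from both
  numerator and denominator.
* **Fold-differences** are reported as ratio of group means (mean of
  per-sample ratios is also emitted; it explodes when a centromeric
  fraction is 0, which monoclonal samples routinely produce).
* **Wilcoxon.** Zero differences dropped; exact distribution up to 25
  untied pairs, else normal approximation with continuity correction
  (delegated to `stats::wilcox.test`; the test suite checks it against
  full enumeration of sign assignments).
* **MAF filter** for AF comparisons is computed on the union of both
  strata (symmetric ascertainment). Threshold comparisons use a 10⁻⁹
  guard so differences exactly at a threshold never count.
* **LD.** Haplotype r² from phased columns with pairwise-complete
  haplotypes; the scan retains a pair if r² ≥ `min_r2` in either stratum
  and keeps the other stratum's computed value; pairs undefined
  (monomorphic) in a stratum are excluded and tallied rather than zeroed.
* **Determinism.** One root seed; per-sample streams derive from it by a
  fixed integer hash, so cohorts are reproducible record-for-record and
  the pipeline's report is byte-identical under a fixed seed.

## Problem sizes used in the tests

Unit tests run on a 60 kb miniature locus (3 J / 3 D / 4 V segments,
~3,000 read pairs per sample). Cohort-scale checks use the full 1.18 Mb
IGH model at 30×: a 20-sample dominance grid for recovery, 20 monoclonal
streams for the heterozygosity direction, 8 samples per stratum for the
fold trend, and 12 + 12 affected samples against 20 random splits of a
24-sample unrecombined cohort for the allele-frequency null envelope.
These sizes keep the whole suite in the minutes range while leaving each
directional test with a comfortable noise margin (measured across
independent seed sets during development).

## What passing tests do and do not show

The simulator reproduces the *mechanism* — haplotype loss, SHM
masquerading as heterozygosity, stratified AF/LD distortion — under clean
mapping. It does not model alignment ambiguity in the highly paralogous V
cluster, reference bias, structural polymorphism of IGH itself,
EBV-integration artifacts, or sequencing error, all of which add noise
(and some bias) in real data. Directional results here say the analysis
detects what its own generative model produces; magnitudes in real cohorts
will differ. In particular, clone counts inferred from ~7 junction pairs
are lower bounds — clones below a few percent of the pool are usually
unseen — and dominant-fraction estimates for single samples should be
read with their binomial error in mind.
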