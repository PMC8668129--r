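# igclone

Detection of somatic V(D)J recombination in short-read whole-genome
sequencing of the immunoglobulin heavy-chain locus (IGH, GRCh38
chr14:105,862,198–107,043,718), and quantification of the damage it does to
genotype, allele-frequency and linkage-disequilibrium estimates.

## Why

Reference cohorts (HapMap, 1000 Genomes, GIAB) sequence DNA from
lymphoblastoid cell lines — immortalized **B cells**. Every B cell has
somatically rearranged IGH: one IGHV, IGHD and IGHJ segment are joined and
the DNA between them (74 Kb to nearly 1 Mb) is excised. A cell line
dominated by one clone is therefore missing a large piece of one
chromosome, so variant callers mis-call heterozygous sites as homozygous
across the excised interval, and somatic hypermutation (SHM) inside the
recombined V segment surfaces as spurious heterozygosity. Population
panels built from such calls carry distorted allele frequencies and LD
over IGH. `igclone` is for anyone consuming or building LCL-derived
call sets over the immunoglobulin loci: it infers each sample's B-cell
clone structure directly from the alignments and measures the downstream
distortion.

## Method

For each sample, from coordinate-level paired-end alignment records:

* **Junction read pairs** — pairs with one mate overlapping an IGHJ
  segment and the other an IGHV segment. Grouped by (J, V) identity,
  each unique pair is a *clone*; its support over the total is the clone
  frequency; the top pair is the *dominant clone* with fraction
  f̂ = max support / Σ support, and the reported somatic deletion is the
  excised span `[end(J), start(V))`.
* **Insert-size signature** — fraction of pairs with insert > 900 bp
  (2× the library insert); a fragment spanning an excised interval maps
  with insert = fragment length + deletion size.
* **Depth signature** — mean coverage over the IGHD region and over the
  dominant clone's excised interval.
* **Heterozygosity partition** — het fraction centromeric vs telomeric of
  the dominant recombined V segment's 3' end (reference start; IGH is
  minus-strand), telomeric side inclusive; paired Wilcoxon across samples.
* **Strata comparisons** — samples binned by percent dominance
  (0,25], (25,50], (50,75], (75,100]; alternate-allele frequencies
  (AF = alt count / 2·n called) and haplotype LD
  r² = D²/(p_A(1−p_A)p_B(1−p_B)) with D = p_AB − p_A·p_B over phased
  haplotypes, compared between the extreme strata (1 Mb pair window,
  r² ≥ 0.01 retention, discordance thresholds 0.05 for AF and 0.1 for r²).

A seeded simulator generates cohorts end-to-end — germline phased SNPs,
clone pools with per-haplotype deletions, SHM, paired-end alignment
records (SAM), emulated genotype calls (VCF) and ground truth — so the
entire analysis is testable without any data download. See the methods
vignette (`vignettes/igh-clonality.Rmd`) for the model and its limits.

## Worked example

```r
library(igclone)
locus <- igh_locus()
cfg   <- sim_config(seed = 42, n_clones = 1)          # one dominant clone
germ  <- simulate_germline(cfg, locus)
truth <- simulate_sample(cfg, locus, germ, 1)
pairs <- simulate_read_pairs(truth, cfg, locus)
prof  <- profile_sample(pairs, locus, "S001")
```

This prints, via the summaries in the example script:

```
sample S001: 1 clone(s), dominant IGHJ3/IGHV4-61 (fraction 1.00)
inferred deletion: chr14:105864240-106784167 (919.9 Kb); truth: IGHJ3/IGHV4-61
large-insert fraction in IGH: 4.58e-04; D-region depth: 6.16x
```

The monoclonal sample is recovered exactly: a single (J, V) clone matching
the simulated truth, a ~920 Kb inferred deletion, a large-insert fraction
far above an unrecombined control (which is 0 in simulation), and IGHD
coverage collapsed from the nominal 30×.

## The analysis workflow

The numbered drivers under `analysis/` run the full study on a simulated
24-sample cohort and write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate_and_detect.R   # cohort, profiles, VCF, deletion BED
Rscript analysis/02_genotype_impact.R       # het partition, Wilcoxon, SHM metrics
Rscript analysis/03_population_metrics.R    # strata, AF and LD comparison
Rscript analysis/04_report.R                # collated report
```

With the default seed the report reads: mean 3.46 clones/sample (range
1–10), 2 monoclonal samples, 12/24 with >50 % dominance; mean dominant
deletion 665 Kb (range 171.2–978.0 Kb); telomeric het fraction 3.23-fold
the centromeric (paired Wilcoxon P = 1.19e-07); dominance vs
recombined-V heterozygosity r = 0.53; and between clonality extremes 761
of 1007 common SNPs (76 %) shift allele frequency by more than 0.05 and
39 % of retained SNP pairs shift r² by more than 0.1 — the same
qualitative picture the method reports on real LCL cohorts, produced here
entirely from the package's own generative model. `run_pipeline()` runs
the same stages as one call.

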