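#!/usr/bin/env Rscript
# Stage 3: population-level distortion.  Bins samples into clonality
# strata and compares allele frequencies and haplotype LD between the
# lowest- and highest-clonality groups.

source("analysis/00_config.R")

profiles <- read.delim(file.path(OUT, "clonality_profiles.tsv"))
callset <- read_vcf(file.path(OUT, "called_genotypes.vcf"))

strata <- assign_strata(profiles)
write.table(strata, file.path(OUT, "strata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(strata$stratum))

low <- strata$sample_id[strata$stratum %in% c("(0,25]", "(25,50]")]
high <- strata$sample_id[strata$stratum == "(75,100]"]
message("comparing ", length(low), " low- vs ", length(high),
        " high-clonality samples")

af <- af_compare(callset, low, high, maf_min = 0.05, diff_threshold = 0.05)
write.table(af$records, file.path(OUT, "af_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("AF: %d of %d common SNPs differ by > 0.05 (%.0f%%)",
                af$n_exceeding, af$n_tested,
                100 * af$n_exceeding / af$n_tested))

ld <- ld_scan_and_compare(callset, low, high, window = 1e6, min_r2 = 0.01,
                          diff_threshold = 0.1)
write.table(ld$histogram, file.path(OUT, "ld_diff_hist.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "LD: %d of %d retained pairs differ in r2 by > 0.1 (%.0f%%); %d pairs undefined in a stratum",
  ld$n_exceeding, ld$n_pairs, 100 * ld$n_exceeding / max(ld$n_pairs, 1),
  ld$n_undefined))
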