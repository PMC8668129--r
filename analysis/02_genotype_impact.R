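#!/usr/bin/env Rscript
# Stage 2: quantify genotype distortion.  Reads the stage-1 profiles and
# call set; partitions heterozygosity at each sample's dominant recombined
# V segment, tests the centromeric deficit, and measures SHM-driven
# heterozygosity inside recombined V segments.

source("analysis/00_config.R")

profiles <- read.delim(file.path(OUT, "clonality_profiles.tsv"))
callset <- read_vcf(file.path(OUT, "called_genotypes.vcf"))

hp <- cohort_het_partition(profiles, callset, LOCUS)
write.table(hp$per_sample, file.path(OUT, "het_partition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "telomeric het fraction %.2f-fold the centromeric (ratio of means; mean of ratios %.2f); paired Wilcoxon P = %.3g over %d samples",
  hp$fold_ratio_of_means, hp$fold_mean_of_ratios, hp$wilcoxon$p_value,
  nrow(hp$per_sample)))

shm <- clonality_het_correlation(profiles, callset, LOCUS)
if (!shm$undefined) {
  message(sprintf(
    "dominant-clone fraction vs het calls in the recombined V: r = %.2f (P = %.3g, n = %d)",
    shm$r, shm$p_value, shm$n))
}
rvo <- recombined_vs_other_het(profiles, callset, LOCUS)
message(sprintf(
  "mean het calls: %.2f in recombined V segments vs %.2f in non-recombined",
  rvo$cohort$mean_recombined_het, rvo$cohort$mean_other_het))
write.table(rvo$per_sample, file.path(OUT, "recombined_het.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
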