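#!/usr/bin/env Rscript
# Stage 4: collate the stage outputs into one plain-text report.

source("analysis/00_config.R")

summ <- read.delim(file.path(OUT, "cohort_summary.tsv"))
hp <- read.delim(file.path(OUT, "het_partition.tsv"))
af <- read.delim(file.path(OUT, "af_comparison.tsv"))
strata <- read.delim(file.path(OUT, "strata.tsv"))

cc <- hp[!is.na(hp$cen_fraction) & !is.na(hp$tel_fraction), ]
wt <- paired_wilcoxon(cc$cen_fraction, cc$tel_fraction)

report <- c(
  sprintf("igclone analysis report (seed %d, %d samples)", SEED, N_SAMPLES),
  "",
  "[clonality]",
  sprintf("mean clones/sample %.2f (range %d-%d); %d monoclonal; %d at >50%% dominance, %d at >75%%",
          summ$mean_n_clones, summ$min_n_clones, summ$max_n_clones,
          summ$n_monoclonal, summ$n_dom_gt50, summ$n_dom_gt75),
  sprintf("mean dominant deletion %.0f Kb (range %.1f-%.1f Kb)",
          summ$mean_del_kb, summ$min_del_kb, summ$max_del_kb),
  "",
  "[genotype impact]",
  sprintf("tel/cen het fold %.2f (ratio of means), paired Wilcoxon P = %.3g",
          mean(cc$tel_fraction) / mean(cc$cen_fraction), wt$p_value),
  "",
  "[population metrics]",
  sprintf("strata sizes: %s",
          paste(names(table(strata$stratum)), table(strata$stratum),
                sep = "=", collapse = ", ")),
  sprintf("AF discordance: %d of %d common SNPs with |dAF| > 0.05",
          sum(af$abs_diff > 0.05), nrow(af)))
writeLines(report, file.path(OUT, "report.txt"))
writeLines(report)
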