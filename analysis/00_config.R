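# Shared settings for the analysis drivers.  Everything downstream of
# 01_simulate_and_detect.R is file-driven: later stages read the tables
# written here rather than re-simulating.

library(igclone)

SEED <- 11L
N_SAMPLES <- 24L
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

LOCUS <- igh_locus()

# mixed-clonality cohort: a third dominated (>= 0.8), a third unskewed
# Dirichlet pools, a third moderately skewed (>= 0.45), clone counts over
# the 1-30 range seen in LCL cohorts
cohort_design <- function(seed, n) {
  set.seed(child_seed <- as.integer((seed * 1000003 + 990 * 7919) %%
                                      2147483629 + 1))
  nc <- sample(1:30, n, replace = TRUE)
  grp <- rep_len(1:3, n)
  df <- ifelse(grp == 1L, pmax(0.80, 1 / nc + 1e-6),
               ifelse(grp == 2L, NA_real_, pmax(0.45, 1 / nc + 1e-6)))
  nc[grp == 1L & nc > 8L] <- 1L + (nc[grp == 1L & nc > 8L] %% 8L)
  data.frame(n_clones = nc, dominant_fraction = df)
}
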