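# Clonality-stratified population metrics: allele frequencies and
# haplotype-based LD r-squared, and their between-stratum differences.

STRATUM_LEVELS <- c("(0,25]", "(25,50]", "(50,75]", "(75,100]")

#' Bin samples into clonality strata
#'
#' Left-open right-closed bins on the percent of V(D)J reads from the
#' dominant clone: (0,25], (25,50], (50,75], (75,100]; monoclonal samples
#' (100%) fall in (75,100].  Undetermined profiles are excluded with a
#' message.
#'
#' @param profiles Profile table or list of `clonality_profile`s.
#' @return `data.frame` with `sample_id`, `dominant_fraction`, `stratum`
#'   (factor with the four levels).
#' @export
assign_strata <- function(profiles) {
  tb <- if (is.data.frame(profiles)) profiles else profiles_table(profiles)
  drop <- tb$status != "ok" | is.na(tb$dominant_fraction)
  if (any(drop)) {
    message(sum(drop), " undetermined profile(s) excluded from strata")
  }
  tb <- tb[!drop, , drop = FALSE]
  stratum <- cut(tb$dominant_fraction * 100, breaks = c(0, 25, 50, 75, 100),
                 labels = STRATUM_LEVELS, right = TRUE)
  data.frame(sample_id = tb$sample_id,
             dominant_fraction = tb$dominant_fraction,
             stratum = stratum, stringsAsFactors = FALSE)
}

# per-site alternate-allele frequency over a sample set (NA when no data)
stratum_af <- function(callset, samples) {
  idx <- match(samples, callset$samples)
  if (anyNA(idx)) stop("unknown sample(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  H <- cbind(callset$h1[, idx, drop = FALSE], callset$h2[, idx, drop = FALSE])
  n <- rowSums(!is.na(H))
  ifelse(n > 0, rowSums(H, na.rm = TRUE) / n, NA_real_)
}

#' Alternate-allele frequency at one site
#'
#' Alternate-allele count over twice the number of samples with a
#' non-missing genotype.
#'
#' @param callset A `phased_callset`.
#' @param samples Sample identifiers.
#' @param site Site index (row of `callset$sites`).
#' @return Frequency in `[0, 1]`, or `NA` when every genotype is missing.
#' @export
allele_frequency <- function(callset, samples, site) {
  stratum_af(callset, samples)[site]
}

#' Compare allele frequencies between two clonality strata
#'
#' Sites are filtered to common SNPs (minor-allele frequency above
#' `maf_min`, computed over the union of both strata's samples); per-site
#' absolute frequency differences above `diff_threshold` are counted and
#' located.
#'
#' @param callset A `phased_callset`.
#' @param low_samples,high_samples Sample id vectors for the two strata.
#' @param maf_min MAF filter (exclusive bound).
#' @param diff_threshold Difference considered discordant (exclusive).
#' @return A list: `records` (`pos`, `af_low`, `af_high`, `abs_diff` for
#'   every site passing the filter with data in both strata), `n_tested`,
#'   `n_exceeding`, `exceeding_pos`.
#' @export
af_compare <- function(callset, low_samples, high_samples, maf_min = 0.05,
                       diff_threshold = 0.05) {
  if (length(low_samples) == 0L || length(high_samples) == 0L) {
    stop("both strata must be non-empty")
  }
  af_low <- stratum_af(callset, low_samples)
  af_high <- stratum_af(callset, high_samples)
  af_all <- stratum_af(callset, union(low_samples, high_samples))
  maf <- pmin(af_all, 1 - af_all)
  keep <- !is.na(maf) & maf > maf_min & !is.na(af_low) & !is.na(af_high)
  records <- data.frame(pos = callset$sites$pos[keep],
                        af_low = af_low[keep], af_high = af_high[keep],
                        abs_diff = abs(af_low[keep] - af_high[keep]))
  # strict comparison with a float guard: a difference exactly at the
  # threshold (common with small rational frequencies) never counts
  exceeding <- records$abs_diff > diff_threshold + 1e-9
  list(records = records, n_tested = nrow(records),
       n_exceeding = sum(exceeding),
       exceeding_pos = records$pos[exceeding])
}

# pairwise-complete haplotype statistics for all site pairs: returns the
# r^2 matrix (NA where a site is monomorphic among shared haplotypes)
hap_r2_matrix <- function(callset, samples) {
  if (!isTRUE(callset$phased)) {
    stop("LD requires phased genotypes; supply a phased callset")
  }
  idx <- match(samples, callset$samples)
  if (anyNA(idx)) stop("unknown sample(s) in stratum")
  H <- cbind(callset$h1[, idx, drop = FALSE], callset$h2[, idx, drop = FALSE])
  U <- !is.na(H)
  X <- H; X[!U] <- 0L
  X <- matrix(as.numeric(X), nrow(X)); Um <- matrix(as.numeric(U), nrow(U))
  n_ab <- Um %*% t(Um)              # haplotypes observed at both sites
  p_ab <- (X %*% t(X)) / n_ab       # freq of alt-alt haplotypes
  p_a <- (X %*% t(Um)) / n_ab       # site-A alt freq among shared haps
  p_b <- (Um %*% t(X)) / n_ab
  D <- p_ab - p_a * p_b
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  r2 <- D * D / denom
  r2[denom <= 0 | n_ab == 0] <- NA_real_
  r2
}

#' Haplotype-based LD r-squared between two sites
#'
#' With haplotype frequencies over the 2n phased haplotypes,
#' `D = p_AB - p_A p_B` and `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#' Haplotypes missing at either site are excluded.
#'
#' @param callset A phased `phased_callset`.
#' @param samples Sample identifiers.
#' @param site_a,site_b Site indices.
#' @return r-squared in `[0, 1]`, or `NA` when a site is monomorphic among
#'   the shared haplotypes.
#' @export
hap_r2 <- function(callset, samples, site_a, site_b) {
  if (!isTRUE(callset$phased)) {
    stop("LD requires phased genotypes; supply a phased callset")
  }
  idx <- match(samples, callset$samples)
  if (anyNA(idx)) stop("unknown sample(s)")
  a <- c(callset$h1[site_a, idx], callset$h2[site_a, idx])
  b <- c(callset$h1[site_b, idx], callset$h2[site_b, idx])
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(NA_real_)
  p_a <- mean(a); p_b <- mean(b)
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  if (denom <= 0) return(NA_real_)
  D <- mean(a == 1L & b == 1L) - p_a * p_b
  D * D / denom
}

#' Scan pairwise LD and compare two strata
#'
#' Computes r-squared for every site pair within `window` bp in each
#' stratum.  A pair is retained when r-squared reaches `min_r2` in either
#' stratum (the other stratum contributes its computed value); pairs where
#' r-squared is undefined in either stratum are excluded and tallied.
#' Differences above `diff_threshold` are counted and the full set binned
#' into a histogram.
#'
#' @inheritParams af_compare
#' @param window Maximum pair distance in bp.
#' @param min_r2 Retention threshold applied within each stratum.
#' @param diff_threshold Absolute r-squared difference considered
#'   discordant.
#' @return A list: `pairs` (`pos_a`, `pos_b`, `r2_low`, `r2_high`,
#'   `abs_diff`), `n_pairs`, `n_exceeding`, `n_undefined`, `histogram`
#'   (bins of `abs_diff`).
#' @export
ld_scan_and_compare <- function(callset, low_samples, high_samples,
                                window = 1e6, min_r2 = 0.01,
                                diff_threshold = 0.1) {
  pos <- callset$sites$pos
  m <- length(pos)
  r2_low <- hap_r2_matrix(callset, low_samples)
  r2_high <- hap_r2_matrix(callset, high_samples)
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  ia <- ut[, 1]; ib <- ut[, 2]
  in_window <- (pos[ib] - pos[ia]) <= window
  ia <- ia[in_window]; ib <- ib[in_window]
  rl <- r2_low[cbind(ia, ib)]; rh <- r2_high[cbind(ia, ib)]
  undefined <- is.na(rl) | is.na(rh)
  retained <- !undefined & (rl >= min_r2 | rh >= min_r2)
  pairs <- data.frame(pos_a = pos[ia[retained]], pos_b = pos[ib[retained]],
                      r2_low = rl[retained], r2_high = rh[retained],
                      abs_diff = abs(rl[retained] - rh[retained]))
  breaks <- seq(0, 1, by = 0.05)
  hist_counts <- if (nrow(pairs)) {
    table(cut(pairs$abs_diff, breaks, include.lowest = TRUE))
  } else table(cut(numeric(0), breaks, include.lowest = TRUE))
  list(pairs = pairs, n_pairs = nrow(pairs),
       n_exceeding = sum(pairs$abs_diff > diff_threshold + 1e-9),
       n_undefined = sum(undefined),
       histogram = data.frame(bin = names(hist_counts),
                              count = as.integer(hist_counts)))
}
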