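# Genotype-distortion metrics: centromeric/telomeric heterozygosity around
# the dominant recombined V segment, SHM-driven heterozygosity inside
# recombined V segments, and their association with clonality.

sample_gt <- function(callset, sample) {
  i <- match(sample, callset$samples)
  if (is.na(i)) stop("sample not in callset: ", sample)
  callset$h1[, i] + callset$h2[, i]
}

#' Partition heterozygosity at a breakpoint
#'
#' Splits the called SNP sites of one sample at the 3' end of the dominant
#' recombined V segment (its reference start on the minus strand) and
#' reports the heterozygous fraction on each side.  The telomeric side is
#' inclusive of the breakpoint position; sites with missing genotypes are
#' excluded from numerator and denominator.
#'
#' @param callset A `phased_callset`.
#' @param sample Sample identifier.
#' @param breakpoint 1-based position; centromeric = `pos < breakpoint`,
#'   telomeric = `pos >= breakpoint`.
#' @param span `genomic_interval` restricting the analyzed sites (the IGH
#'   locus span, normally).
#' @return A list of class `het_partition` with `cen` and `tel`
#'   (`n_het`, `n_total`, `fraction`; `fraction` is `NA` when a side has no
#'   called site) and the inputs.
#' @export
partition_het <- function(callset, sample, breakpoint, span) {
  if (breakpoint <= span$start || breakpoint > span$end) {
    stop("breakpoint must lie within the analyzed span")
  }
  gt <- sample_gt(callset, sample)
  pos <- callset$sites$pos
  keep <- !is.na(gt) & pos > span$start & pos <= span$end
  side <- function(sel) {
    n <- sum(sel); h <- sum(gt[sel] == 1L)
    list(n_het = h, n_total = n, fraction = if (n > 0) h / n else NA_real_)
  }
  structure(list(sample_id = sample, breakpoint = breakpoint,
                 cen = side(keep & pos < breakpoint),
                 tel = side(keep & pos >= breakpoint)),
            class = "het_partition")
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Compares paired per-sample fractions (e.g. centromeric vs telomeric
#' heterozygosity).  Zero differences are dropped before testing; the exact
#' distribution is used for up to 25 informative pairs when ranks are
#' untied, otherwise the normal approximation with continuity correction.
#'
#' @param x,y Paired numeric vectors (same length, >= 2).
#' @return A list: `p_value`, `statistic` (V), `n_effective` (pairs with a
#'   nonzero difference), `all_zero`.  When every difference is zero the
#'   p-value is 1 with `all_zero = TRUE` and a warning.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors of unequal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero")
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                all_zero = TRUE))
  }
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided",
                                            mu = 0, exact = exact,
                                            correct = TRUE))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       n_effective = length(d), all_zero = FALSE)
}

#' Heterozygous calls within one gene segment
#'
#' @param callset A `phased_callset`.
#' @param sample Sample identifier.
#' @param segment Single-row gene-segment `data.frame`.
#' @return Count of het-called sites whose position overlaps the segment
#'   interval (boundary base included).
#' @export
het_count_in_segment <- function(callset, sample, segment) {
  gt <- sample_gt(callset, sample)
  pos <- callset$sites$pos
  sum(!is.na(gt) & gt == 1L & pos > segment$start[1] & pos <= segment$end[1])
}

#' Correlation between clonality and recombined-V heterozygosity
#'
#' Pearson correlation, across samples, between the dominant-clone fraction
#' and the number of heterozygous calls inside the dominant recombined V
#' segment — the SHM signature: mutations on the expressed haplotype
#' surface as heterozygous calls in proportion to the clone's share of
#' reads.
#'
#' @param profiles Profile table ([profiles_table()]) or list of profiles.
#' @param callset A `phased_callset`.
#' @param locus A `locus_definition` resolving dominant V names.
#' @return A list: `r`, `p_value`, `n`, `het_counts`, `fractions`;
#'   `undefined = TRUE` (with `r = NA`) when either vector has zero
#'   variance.
#' @export
clonality_het_correlation <- function(profiles, callset, locus) {
  tb <- if (is.data.frame(profiles)) profiles else profiles_table(profiles)
  tb <- tb[tb$status == "ok" & !is.na(tb$dominant_v) &
             tb$sample_id %in% callset$samples, , drop = FALSE]
  if (nrow(tb) < 3L) stop("need at least 3 profiled samples with genotypes")
  seg <- locus$segments
  het <- vapply(seq_len(nrow(tb)), function(i) {
    het_count_in_segment(callset, tb$sample_id[i],
                         seg[match(tb$dominant_v[i], seg$name), ])
  }, 0)
  f <- tb$dominant_fraction
  if (stats::sd(het) == 0 || stats::sd(f) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(tb),
                het_counts = het, fractions = f, undefined = TRUE))
  }
  ct <- stats::cor.test(f, het, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(tb),
       het_counts = het, fractions = f, undefined = FALSE)
}

#' Heterozygosity in recombined vs non-recombined V segments
#'
#' Per sample: the het count inside the dominant recombined V segment, and
#' the mean het count over all other V segments; plus their cohort means.
#'
#' @inheritParams clonality_het_correlation
#' @return A list with `per_sample` (`sample_id`, `recombined_het`,
#'   `other_het_mean`) and `cohort` (means of both columns).
#' @export
recombined_vs_other_het <- function(profiles, callset, locus) {
  tb <- if (is.data.frame(profiles)) profiles else profiles_table(profiles)
  tb <- tb[tb$status == "ok" & !is.na(tb$dominant_v) &
             tb$sample_id %in% callset$samples, , drop = FALSE]
  seg <- locus$segments
  vs <- seg[seg$family == "V", , drop = FALSE]
  per <- do.call(rbind, lapply(seq_len(nrow(tb)), function(i) {
    dom <- tb$dominant_v[i]
    rec <- het_count_in_segment(callset, tb$sample_id[i],
                                vs[match(dom, vs$name), ])
    others <- vs[vs$name != dom, , drop = FALSE]
    oth <- vapply(seq_len(nrow(others)), function(k) {
      het_count_in_segment(callset, tb$sample_id[i], others[k, ])
    }, 0)
    data.frame(sample_id = tb$sample_id[i], recombined_het = rec,
               other_het_mean = mean(oth), stringsAsFactors = FALSE)
  }))
  list(per_sample = per,
       cohort = data.frame(mean_recombined_het = mean(per$recombined_het),
                           mean_other_het = mean(per$other_het_mean)))
}

#' Cohort heterozygosity partition with group fold-differences
#'
#' Runs [partition_het()] for every profiled sample at its own dominant-V
#' breakpoint and reports the paired Wilcoxon test plus the
#' telomeric/centromeric fold-difference.  Folds are reported as the ratio
#' of group means (a mean of per-sample ratios is also returned).
#'
#' @inheritParams clonality_het_correlation
#' @param span Analyzed interval (defaults to the locus span).
#' @return A list: `per_sample` table with cen/tel fractions, `wilcoxon`,
#'   `fold_ratio_of_means`, `fold_mean_of_ratios`.
#' @export
cohort_het_partition <- function(profiles, callset, locus,
                                 span = locus$locus) {
  tb <- if (is.data.frame(profiles)) profiles else profiles_table(profiles)
  tb <- tb[tb$status == "ok" & !is.na(tb$dominant_v) &
             tb$sample_id %in% callset$samples, , drop = FALSE]
  seg <- locus$segments
  per <- do.call(rbind, lapply(seq_len(nrow(tb)), function(i) {
    bp <- seg$start[match(tb$dominant_v[i], seg$name)] + 1L  # 1-based
    hp <- partition_het(callset, tb$sample_id[i], bp, span)
    data.frame(sample_id = tb$sample_id[i],
               dominant_fraction = tb$dominant_fraction[i],
               breakpoint = bp,
               cen_fraction = hp$cen$fraction, tel_fraction = hp$tel$fraction,
               stringsAsFactors = FALSE)
  }))
  cc <- per[!is.na(per$cen_fraction) & !is.na(per$tel_fraction), ,
            drop = FALSE]
  wt <- if (nrow(cc) >= 2L) paired_wilcoxon(cc$cen_fraction, cc$tel_fraction)
        else list(p_value = NA_real_, statistic = NA_real_,
                  n_effective = 0L, all_zero = NA)
  ratios <- cc$tel_fraction[cc$cen_fraction > 0] /
    cc$cen_fraction[cc$cen_fraction > 0]
  list(per_sample = per, wilcoxon = wt,
       fold_ratio_of_means = mean(cc$tel_fraction) / mean(cc$cen_fraction),
       fold_mean_of_ratios = if (length(ratios)) mean(ratios) else NA_real_)
}
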