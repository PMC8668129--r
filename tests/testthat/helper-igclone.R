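# Shared fixtures and independent oracles for the test suite.  The toy
# locus is a 60 kb miniature of the IGH layout (J < D < V on one
# chromosome) that keeps simulations fast; tests of the published
# coordinates use igh_locus() directly.

toy_segments <- function() {
  gene_segments(
    name = c("IGHJ1", "IGHJ2", "IGHJ3",
             "IGHD7-27", "IGHD3-10", "IGHD1-1",
             "IGHV6-1", "IGHV3-23", "IGHV1-69", "IGHV3-74"),
    chrom = "chrT",
    start = c(2950, 2250, 1550,
              3100, 4500, 6000,
              8000, 20000, 40000, 55000),
    end = c(3000, 2300, 1600,
            3120, 4520, 6030,
            8300, 20450, 40450, 55450))
}

toy_locus <- function() {
  locus_definition(
    chrom = "chrT",
    locus = genomic_interval("chrT", 0, 60000),
    j_region = genomic_interval("chrT", 0, 3000),
    d_region = genomic_interval("chrT", 3000, 8000),
    v_region = genomic_interval("chrT", 8000, 60000),
    segments = toy_segments())
}

toy_config <- function(snp_density = 1 / 200, ...) {
  sim_config(snp_density = snp_density, ...)
}

# one crafted read pair per call; defaults make an ordinary proper pair
make_pair <- function(start1, start2, chrom = "chrT", width1 = 150,
                      width2 = 150, mapq1 = 60, mapq2 = 60,
                      duplicate = FALSE, secondary = FALSE) {
  data.frame(sample_id = "crafted", chrom = chrom,
             start1 = start1, end1 = start1 + width1, clip1 = "none",
             start2 = start2, end2 = start2 + width2, clip2 = "none",
             mapq1 = mapq1, mapq2 = mapq2,
             insert_size = start2 + width2 - start1,
             proper = (start2 + width2 - start1) <= 600,
             duplicate = duplicate, secondary = secondary,
             clone_id = "crafted", hap = 1L,
             qname = sprintf("crafted.%09d", start1 * 1000 + start2 %% 1000),
             stringsAsFactors = FALSE)
}

make_pairs <- function(...) do.call(rbind, list(...))

# brute-force V(D)J pair caller: explicit loops over pairs and segments,
# replicating the documented tie-breaks, independent of the IRanges path
brute_force_vdj <- function(pairs, locus, min_mapq = 0) {
  seg <- locus$segments
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (p$duplicate || p$secondary) next
    if (p$chrom != locus$chrom) next
    if (p$mapq1 < min_mapq || p$mapq2 < min_mapq) next
    best <- function(s, e, family) {
      hit <- NULL; hw <- 0
      for (k in seq_len(nrow(seg))) {
        if (seg$family[k] != family) next
        w <- min(e, seg$end[k]) - max(s, seg$start[k])
        if (w <= 0) next
        if (w > hw || (w == hw && !is.null(hit) && seg$name[k] < hit)) {
          hit <- seg$name[k]; hw <- w
        }
      }
      hit
    }
    j1 <- best(p$start1, p$end1, "J"); v1 <- best(p$start1, p$end1, "V")
    j2 <- best(p$start2, p$end2, "J"); v2 <- best(p$start2, p$end2, "V")
    if (!is.null(j1) && !is.null(v2) && is.null(v1) && is.null(j2)) {
      out[[length(out) + 1L]] <- c(j1, v2)
    } else if (!is.null(j2) && !is.null(v1) && is.null(v2) && is.null(j1)) {
      out[[length(out) + 1L]] <- c(j2, v1)
    }
  }
  if (!length(out)) {
    return(data.frame(j_name = character(), v_name = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(j_name = m[, 1], v_name = m[, 2], stringsAsFactors = FALSE)
}

# direct 2x2 haplotype-table r^2: count the four haplotype classes
brute_force_r2 <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  pa <- (n11 + n10) / n; pb <- (n11 + n01) / n
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- n11 / n - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# exact two-sided signed-rank p by enumeration of all sign assignments
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12))
}

# small hand-built phased callset
toy_callset <- function(pos, h1, h2, samples = paste0("S", seq_len(ncol(h1))),
                        chrom = "chrT") {
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep("A", length(pos)), alt = rep("G", length(pos)),
                      stringsAsFactors = FALSE)
  phased_callset(sites, h1, h2, samples)
}
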