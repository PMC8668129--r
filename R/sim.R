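# Synthetic LCL cohort simulator.  A sample is a pool of B-cell clones; each
# clone carries a V(D)J deletion on the expressed haplotype (hap 1) and, by
# default, a D-J join on the other (hap 2).  Reads are emitted directly as
# reference-coordinate alignment records: no base-level sequence is modelled.

child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(index)) %%
               2147483629 + 1)
}

#' Simulation configuration
#'
#' Defaults describe a standard PCR-free short-read library over the IGH
#' locus: 2x150 bp reads, ~450 bp fragments, 30-fold coverage.
#'
#' @param seed Integer root seed; every per-sample stream is derived from it.
#' @param n_samples Number of samples in the cohort.
#' @param snp_density Germline SNPs per bp (default 1/1000).
#' @param allele_freq_dist Either `c(a, b)` Beta parameters for population
#'   allele frequencies, or a single number for a fixed frequency.
#' @param n_clones Clones per sample; 0 simulates an unrecombined control
#'   sample (pure germline, no deletions).
#' @param dominant_fraction Fraction of cells in the top clone, in
#'   `(0, 1]`, or `NA` to draw fractions from a symmetric Dirichlet.
#' @param dirichlet_alpha Concentration used when `dominant_fraction` is `NA`.
#' @param read_length,fragment_mean,fragment_sd Library geometry in bp.
#'   Fragment lengths are Normal, truncated to
#'   `[2 * read_length, fragment_mean + 3 * fragment_sd]`.
#' @param coverage Target fold coverage over deletion-free sequence.
#' @param shm_rate Somatic hypermutations per bp within the recombined V
#'   segment of each clone.
#' @param second_allele_mode `"dj_only"` (default): the non-expressed
#'   haplotype carries only a D-J join confined to the D region;
#'   `"full_vdj"`: it carries an independently drawn V-DJ join.
#' @param mapq_default Mapping quality written on simulated records.
#' @param het_threshold,min_depth Genotype-call emulation: a site is called
#'   heterozygous when the minor-allele read fraction is at least
#'   `het_threshold` and depth is at least `min_depth`.
#' @param min_clip Minimum mapped bases for a junction-clipped read to be
#'   emitted (shorter mapped stubs would not align in practice).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 1L, snp_density = 1 / 1000,
                       allele_freq_dist = c(1, 1), n_clones = 1L,
                       dominant_fraction = NA_real_, dirichlet_alpha = 1,
                       read_length = 150L, fragment_mean = 450L,
                       fragment_sd = 50L, coverage = 30,
                       shm_rate = 5e-3,
                       second_allele_mode = c("dj_only", "full_vdj"),
                       mapq_default = 60L, het_threshold = 0.2,
                       min_depth = 4L, min_clip = 30L) {
  second_allele_mode <- match.arg(second_allele_mode)
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              snp_density = snp_density,
              allele_freq_dist = allele_freq_dist,
              n_clones = as.integer(n_clones),
              dominant_fraction = dominant_fraction,
              dirichlet_alpha = dirichlet_alpha,
              read_length = as.integer(read_length),
              fragment_mean = as.numeric(fragment_mean),
              fragment_sd = as.numeric(fragment_sd),
              coverage = coverage, shm_rate = shm_rate,
              second_allele_mode = second_allele_mode,
              mapq_default = as.integer(mapq_default),
              het_threshold = het_threshold, min_depth = as.integer(min_depth),
              min_clip = as.integer(min_clip))
  if (cfg$coverage <= 0) stop("coverage must be positive")
  if (cfg$fragment_mean <= 2 * cfg$read_length) {
    stop("fragment_mean must exceed 2 * read_length")
  }
  if (!is.na(cfg$dominant_fraction) &&
      (cfg$dominant_fraction <= 0 || cfg$dominant_fraction > 1)) {
    stop("dominant_fraction must lie in (0, 1]")
  }
  if (cfg$n_clones < 0) stop("n_clones must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a phased call set
#'
#' The shared container for germline truth and emulated genotype calls:
#' biallelic SNP sites with one pair of phased haplotype alleles (0 = ref,
#' 1 = alt, `NA` = missing) per sample.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (positions strictly increasing).
#' @param h1,h2 Site-by-sample 0/1 matrices, one per haplotype.
#' @param samples Sample identifiers (column order of `h1`/`h2`).
#' @param phased Whether haplotype assignment is meaningful.
#' @return A list of class `phased_callset`.
#' @export
phased_callset <- function(sites, h1, h2, samples, phased = TRUE) {
  stopifnot(nrow(sites) == nrow(h1), nrow(sites) == nrow(h2),
            ncol(h1) == length(samples), ncol(h2) == length(samples))
  if (is.unsorted(sites$pos, strictly = TRUE)) {
    stop("callset positions must be strictly increasing")
  }
  colnames(h1) <- colnames(h2) <- samples
  structure(list(sites = sites, h1 = h1, h2 = h2, samples = samples,
                 phased = phased),
            class = "phased_callset")
}

#' Genotype codes of a call set
#' @param callset A `phased_callset`.
#' @return Site-by-sample matrix: 0 hom-ref, 1 het, 2 hom-alt, `NA` missing.
#' @export
genotype_codes <- function(callset) callset$h1 + callset$h2

#' Simulate cohort germline variation
#'
#' SNP positions are placed uniformly at `snp_density` over the locus (site
#' count is Poisson); each site gets a population alternate-allele frequency
#' from the configured Beta distribution, and per-sample phased genotypes are
#' drawn binomially under Hardy-Weinberg.
#'
#' @param config A `sim_config`.
#' @param locus A `locus_definition`.
#' @return A `phased_callset` whose `sites` carry the population frequency
#'   in column `af`.
#' @export
simulate_germline <- function(config, locus) {
  L <- interval_width(locus$locus)
  if (L <= 0) stop("zero-length locus")
  set.seed(child_seed(config$seed, 0L))
  n_sites <- stats::rpois(1L, L * config$snp_density)
  pos <- sort(sample.int(L, n_sites)) + locus$locus$start  # 1-based positions
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  afd <- config$allele_freq_dist
  af <- if (length(afd) == 1L) rep(afd, n_sites) else
    stats::rbeta(n_sites, afd[1], afd[2])
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  h1 <- matrix(stats::rbinom(n_sites * config$n_samples, 1L, af),
               nrow = n_sites)
  h2 <- matrix(stats::rbinom(n_sites * config$n_samples, 1L, af),
               nrow = n_sites)
  sites <- data.frame(chrom = locus$chrom, pos = pos, ref = unname(ref),
                      alt = unname(alt), af = af, stringsAsFactors = FALSE)
  phased_callset(sites, h1, h2, samples)
}

# clone fractions: explicit dominant + uniform remainder, or Dirichlet
clone_fractions <- function(n, dominant_fraction, alpha) {
  if (!is.na(dominant_fraction)) {
    if (n > 1 && dominant_fraction < 1 / n) {
      stop("dominant_fraction ", dominant_fraction,
           " cannot be dominant among ", n, " clones")
    }
    if (n == 1) return(1)
    c(dominant_fraction, rep((1 - dominant_fraction) / (n - 1), n - 1))
  } else {
    g <- stats::rgamma(n, shape = alpha)
    g / sum(g)
  }
}

#' Simulate the clone pool of one sample
#'
#' Each clone independently selects one IGHJ and one IGHV segment (uniformly)
#' for the expressed haplotype; the excised interval runs from the J
#' segment's end to the V segment's start.  The second haplotype follows
#' `config$second_allele_mode`.  Somatic hypermutations are placed uniformly
#' within the recombined V segment at `shm_rate` per bp.
#'
#' @param config A `sim_config`.
#' @param locus A `locus_definition` with at least one J and one V segment.
#' @param seed Stream seed for this sample.
#' @return A list with `clones` (one row per clone: fractions, selected
#'   segments, per-haplotype deletion intervals) and `shm` (`clone_id`,
#'   `pos`).
#' @export
simulate_clone_pool <- function(config, locus, seed = config$seed) {
  seg <- locus$segments
  js <- seg[seg$family == "J", , drop = FALSE]
  vs <- seg[seg$family == "V", , drop = FALSE]
  ds <- seg[seg$family == "D", , drop = FALSE]
  if (nrow(js) == 0L || nrow(vs) == 0L) {
    stop("locus needs at least one J and one V segment")
  }
  set.seed(seed)
  n <- config$n_clones
  if (n == 0L) {  # unrecombined control sample
    clones <- data.frame(clone_id = "germline", fraction = 1,
                         j_name = NA_character_, v_name = NA_character_,
                         del1_start = NA_real_, del1_end = NA_real_,
                         j2_name = NA_character_, v2_name = NA_character_,
                         del2_start = NA_real_, del2_end = NA_real_,
                         stringsAsFactors = FALSE)
    return(list(clones = clones,
                shm = data.frame(clone_id = character(), pos = numeric())))
  }
  frac <- clone_fractions(n, config$dominant_fraction, config$dirichlet_alpha)
  ji <- sample.int(nrow(js), n, replace = TRUE)
  vi <- sample.int(nrow(vs), n, replace = TRUE)
  j2i <- sample.int(nrow(js), n, replace = TRUE)
  clones <- data.frame(clone_id = sprintf("c%02d", seq_len(n)),
                       fraction = frac,
                       j_name = js$name[ji], v_name = vs$name[vi],
                       del1_start = js$end[ji], del1_end = vs$start[vi],
                       stringsAsFactors = FALSE)
  if (config$second_allele_mode == "dj_only") {
    # D-J join: lose DNA between the second J and a selected D segment
    d2i <- sample.int(nrow(ds), n, replace = TRUE)
    clones$j2_name <- js$name[j2i]
    clones$v2_name <- ds$name[d2i]
    clones$del2_start <- js$end[j2i]
    clones$del2_end <- ds$start[d2i]
  } else {
    v2i <- sample.int(nrow(vs), n, replace = TRUE)
    clones$j2_name <- js$name[j2i]
    clones$v2_name <- vs$name[v2i]
    clones$del2_start <- js$end[j2i]
    clones$del2_end <- vs$start[v2i]
  }
  # guard against degenerate (empty) second deletions
  bad2 <- clones$del2_end < clones$del2_start
  clones$del2_end[bad2] <- clones$del2_start[bad2]
  # SHM within the recombined V segment of the expressed haplotype
  shm <- do.call(rbind, lapply(seq_len(n), function(k) {
    v <- vs[vi[k], ]
    w <- v$end - v$start
    m <- stats::rbinom(1L, w, config$shm_rate)
    if (m == 0L) return(NULL)
    data.frame(clone_id = clones$clone_id[k],
               pos = v$start + sort(sample.int(w, m)),  # 1-based positions
               stringsAsFactors = FALSE)
  }))
  if (is.null(shm)) shm <- data.frame(clone_id = character(), pos = numeric())
  list(clones = clones, shm = shm)
}

#' Assemble the ground truth of one simulated sample
#'
#' @param config A `sim_config`.
#' @param locus A `locus_definition`.
#' @param germline A germline `phased_callset` covering the cohort.
#' @param sample_index Column of `germline` this sample uses.
#' @param n_clones,dominant_fraction Optional per-sample overrides of the
#'   config values.
#' @return A list of class `sim_truth`: sample id, clone table, SHM table,
#'   this sample's germline haplotypes, and the dominant clone's identity and
#'   deletion interval.
#' @export
simulate_sample <- function(config, locus, germline, sample_index,
                            n_clones = NULL, dominant_fraction = NULL) {
  cfg <- config
  if (!is.null(n_clones)) cfg$n_clones <- as.integer(n_clones)
  if (!is.null(dominant_fraction)) cfg$dominant_fraction <- dominant_fraction
  seed <- child_seed(config$seed, sample_index)
  pool <- simulate_clone_pool(cfg, locus, seed = seed)
  # drop SHM positions colliding with germline SNP sites (vanishingly rare);
  # keeps the allele bookkeeping at a site unambiguous
  pool$shm <- pool$shm[!(pool$shm$pos %in% germline$sites$pos), , drop = FALSE]
  dom <- which.max(pool$clones$fraction)
  structure(list(sample_id = germline$samples[sample_index],
                 sample_index = sample_index,
                 seed = seed,
                 config = cfg,
                 clones = pool$clones, shm = pool$shm,
                 g1 = germline$h1[, sample_index],
                 g2 = germline$h2[, sample_index],
                 dominant_clone_id = pool$clones$clone_id[dom],
                 dominant_j = pool$clones$j_name[dom],
                 dominant_v = pool$clones$v_name[dom],
                 dominant_fraction = pool$clones$fraction[dom],
                 deletion = c(pool$clones$del1_start[dom],
                              pool$clones$del1_end[dom])),
            class = "sim_truth")
}

# map template intervals to reference coordinates around one deletion,
# clipping reads that straddle the junction to their larger mapped side.
# a, b: 0-based template interval (relative to locus start); returns ref
# start/end (absolute) or NA when the mapped stub is shorter than min_clip.
map_template <- function(a, b, jt, dlen, origin, min_clip) {
  start <- numeric(length(a)); end <- numeric(length(a))
  left <- b <= jt          # entirely before the junction
  right <- a >= jt         # entirely after
  mid <- !left & !right    # straddles: clip to the larger side
  start[left] <- a[left]; end[left] <- b[left]
  start[right] <- a[right] + dlen; end[right] <- b[right] + dlen
  if (any(mid)) {
    lw <- jt - a[mid]; rw <- b[mid] - jt
    keep_left <- lw >= rw
    start[mid] <- ifelse(keep_left, a[mid], jt + dlen)
    end[mid] <- ifelse(keep_left, jt, b[mid] + dlen)
    start[which(mid)[pmax(lw, rw) < min_clip]] <- NA_real_
  }
  clip <- rep("none", length(a))
  if (any(mid)) clip[mid] <- ifelse(jt - a[mid] >= b[mid] - jt, "right", "left")
  list(start = origin + start, end = origin + end, clip = clip)
}

#' Emit paired-end alignment records for one sample
#'
#' Fragments are sampled along each clone-by-haplotype post-deletion
#' template in proportion to clone fraction, to the configured coverage.  A
#' fragment spanning the deletion junction yields a pair whose reference
#' insert size is the fragment length plus the deletion size; a read
#' straddling the junction itself is emitted clipped to its larger mapped
#' side (the soft-clipped alignment an aligner would report), and dropped if
#' fewer than `min_clip` bases remain mapped.  No emitted interval overlaps
#' the deleted interval of the template it came from.
#'
#' @param truth A `sim_truth`.
#' @param config A `sim_config` (normally `truth$config`).
#' @param locus A `locus_definition`.
#' @return A `data.frame` of read pairs: mate intervals (0-based half-open),
#'   mapping qualities, outer insert size, flags, and the originating
#'   `clone_id`/`hap` (simulation provenance used by the genotype-call
#'   emulator).
#' @export
simulate_read_pairs <- function(truth, config = truth$config, locus) {
  set.seed(child_seed(truth$seed, 1L))
  rl <- config$read_length
  L <- interval_width(locus$locus)
  origin <- locus$locus$start
  fmin <- 2 * rl
  fmax <- config$fragment_mean + 3 * config$fragment_sd
  out <- vector("list", 2L * nrow(truth$clones))
  k <- 0L
  for (ci in seq_len(nrow(truth$clones))) {
    cl <- truth$clones[ci, ]
    for (hap in 1:2) {
      ds <- if (hap == 1) cl$del1_start else cl$del2_start
      de <- if (hap == 1) cl$del1_end else cl$del2_end
      has_del <- !is.na(ds) && !is.na(de) && de > ds
      dlen <- if (has_del) de - ds else 0
      jt <- if (has_del) ds - origin else Inf
      Lt <- L - dlen
      n <- stats::rpois(1L, config$coverage * cl$fraction * Lt / (4 * rl))
      if (n == 0L) next
      flen <- round(stats::rnorm(n, config$fragment_mean, config$fragment_sd))
      flen <- pmin(pmax(flen, fmin), fmax, Lt)
      t0 <- floor(stats::runif(n, 0, Lt - flen + 1))
      m1 <- map_template(t0, t0 + rl, jt, dlen, origin, config$min_clip)
      m2 <- map_template(t0 + flen - rl, t0 + flen, jt, dlen, origin,
                         config$min_clip)
      ok <- !is.na(m1$start) & !is.na(m2$start)
      if (!any(ok)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = truth$sample_id, chrom = locus$chrom,
        start1 = m1$start[ok], end1 = m1$end[ok], clip1 = m1$clip[ok],
        start2 = m2$start[ok], end2 = m2$end[ok], clip2 = m2$clip[ok],
        mapq1 = config$mapq_default, mapq2 = config$mapq_default,
        insert_size = m2$end[ok] - m1$start[ok],
        proper = (m2$end[ok] - m1$start[ok]) <= fmax,
        duplicate = FALSE, secondary = FALSE,
        clone_id = cl$clone_id, hap = hap,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start1 = numeric(), end1 = numeric(),
                      clip1 = character(), start2 = numeric(),
                      end2 = numeric(), clip2 = character(),
                      mapq1 = integer(), mapq2 = integer(),
                      insert_size = numeric(), proper = logical(),
                      duplicate = logical(), secondary = logical(),
                      clone_id = character(), hap = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, out[seq_len(k)])
  pairs <- pairs[order(pairs$start1, pairs$start2), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$qname <- sprintf("%s.%06d", pairs$sample_id, seq_len(nrow(pairs)))
  pairs
}

#' Emulate genotype calls from simulated reads
#'
#' Accumulates per-site allele observations from every read covering the
#' site: a read contributes the germline allele of its originating
#' haplotype, or the mutant allele where the read comes from the recombined
#' haplotype of a clone carrying an SHM at that position.  Call rule: depth
#' 0 is missing; minor-allele fraction >= `het_threshold` at depth >=
#' `min_depth` is heterozygous; anything else is homozygous for the majority
#' allele.
#'
#' @param pairs Read pairs from [simulate_read_pairs()] (must carry the
#'   `clone_id`/`hap` provenance columns).
#' @param truth The matching `sim_truth`.
#' @param sites Site table: `chrom`, `pos`, plus `type` (`"germline"` or
#'   `"shm"`) and, for germline rows, `gidx` (index into the sample's
#'   germline haplotype vectors).  See [cohort_sites()].
#' @param config A `sim_config`.
#' @param locus A `locus_definition` (site positions must fall inside it).
#' @return A list with `gt` (0/1/2/`NA` per site), `h1`/`h2` (phased
#'   alleles), `depth` and `alt_frac`.
#' @export
emulate_genotype_calls <- function(pairs, truth, sites,
                                   config = truth$config, locus) {
  if (any(sites$pos <= locus$locus$start | sites$pos > locus$locus$end)) {
    stop("sites outside the locus span")
  }
  ns <- nrow(sites)
  mates <- data.frame(
    start = c(pairs$start1, pairs$start2), end = c(pairs$end1, pairs$end2),
    clone = c(pairs$clone_id, pairs$clone_id), hap = c(pairs$hap, pairs$hap))
  depth <- integer(ns); alt <- integer(ns)
  if (nrow(mates) > 0L) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos, sites$pos),
      IRanges::IRanges(mates$start + 1L, mates$end))
    si <- S4Vectors::queryHits(hits); mi <- S4Vectors::subjectHits(hits)
    hap <- mates$hap[mi]
    g <- integer(length(si))
    isg <- sites$type[si] == "germline"
    gidx <- sites$gidx[si]
    g[isg & hap == 1] <- truth$g1[gidx[isg & hap == 1]]
    g[isg & hap == 2] <- truth$g2[gidx[isg & hap == 2]]
    if (nrow(truth$shm) > 0L) {
      shm_key <- paste(truth$shm$clone_id, truth$shm$pos)
      hit_key <- paste(mates$clone[mi], sites$pos[si])
      g[hap == 1 & hit_key %in% shm_key] <- 1L
    }
    depth <- tabulate(si, nbins = ns)
    alt <- tabulate(si[g == 1L], nbins = ns)
  }
  altf <- ifelse(depth > 0, alt / depth, NA_real_)
  minor <- pmin(altf, 1 - altf)
  gt <- ifelse(depth == 0, NA_integer_,
               ifelse(minor >= config$het_threshold & depth >= config$min_depth,
                      1L, ifelse(altf > 0.5, 2L, 0L)))
  # phase: true phase where the call matches a germline het; SHM alleles ride
  # the recombined haplotype (hap 1); other de-novo hets default to 1|0
  h1 <- ifelse(gt == 2L, 1L, 0L); h2 <- h1
  het <- which(gt == 1L)
  for (i in het) {
    if (sites$type[i] == "germline" &&
        truth$g1[sites$gidx[i]] + truth$g2[sites$gidx[i]] == 1L) {
      h1[i] <- truth$g1[sites$gidx[i]]; h2[i] <- truth$g2[sites$gidx[i]]
    } else {
      h1[i] <- 1L; h2[i] <- 0L
    }
  }
  h1[is.na(gt)] <- NA_integer_; h2[is.na(gt)] <- NA_integer_
  list(gt = gt, h1 = h1, h2 = h2, depth = depth, alt_frac = altf)
}

#' Cohort site table: germline SNPs plus discovered SHM positions
#'
#' Builds the union of the cohort's germline SNP sites and every SHM
#' position carried by any sample's clones, mirroring what joint variant
#' discovery over the cohort would report.  SHM sites are hom-ref in the
#' germline of every sample.
#'
#' @param germline Germline `phased_callset`.
#' @param truths List of `sim_truth` objects.
#' @return A site `data.frame` with `type` and `gidx` columns as consumed by
#'   [emulate_genotype_calls()].
#' @export
cohort_sites <- function(germline, truths) {
  g <- germline$sites
  g$type <- "germline"; g$gidx <- seq_len(nrow(g))
  shm_pos <- sort(unique(unlist(lapply(truths, function(t) t$shm$pos))))
  shm_pos <- setdiff(shm_pos, g$pos)
  if (length(shm_pos)) {
    s <- data.frame(chrom = g$chrom[1], pos = shm_pos, ref = "A", alt = "G",
                    af = 0, type = "shm", gidx = NA_integer_,
                    stringsAsFactors = FALSE)
    g <- rbind(g, s)
  }
  g <- g[order(g$pos), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Simulate a cohort end to end
#'
#' Draws cohort germline variation, per-sample clone pools, read pairs and
#' emulated genotype calls.  Per-sample read pairs are passed to `pair_fun`
#' (if given) and then discarded unless `keep_pairs` is set, so large
#' cohorts stay in memory.
#'
#' @param config A `sim_config`; `n_samples` sets the cohort size.
#' @param locus A `locus_definition`.
#' @param clone_params Optional `data.frame` with per-sample `n_clones` and
#'   `dominant_fraction` (NA entries fall back to the config).
#' @param pair_fun Optional `function(pairs, truth)` evaluated per sample;
#'   results are returned in `pair_results`.
#' @param keep_pairs Keep every sample's read pairs (memory-hungry).
#' @return A list: `germline` and `called` (`phased_callset`s over the same
#'   site table), `sites`, `truths`, `pair_results`, `pairs`.
#' @export
simulate_cohort <- function(config, locus, clone_params = NULL,
                            pair_fun = NULL, keep_pairs = FALSE) {
  germ <- simulate_germline(config, locus)
  n <- config$n_samples
  if (!is.null(clone_params)) stopifnot(nrow(clone_params) == n)
  truths <- lapply(seq_len(n), function(i) {
    nc <- if (is.null(clone_params)) NULL else {
      v <- clone_params$n_clones[i]; if (is.na(v)) NULL else v
    }
    df <- if (is.null(clone_params) ||
              is.null(clone_params$dominant_fraction)) NULL else {
      v <- clone_params$dominant_fraction[i]; if (is.na(v)) NULL else v
    }
    simulate_sample(config, locus, germ, i, n_clones = nc,
                    dominant_fraction = df)
  })
  sites <- cohort_sites(germ, truths)
  ns <- nrow(sites)
  h1 <- matrix(NA_integer_, ns, n); h2 <- matrix(NA_integer_, ns, n)
  gt <- matrix(NA_integer_, ns, n)
  pair_results <- vector("list", n)
  pairs_keep <- if (keep_pairs) vector("list", n) else NULL
  for (i in seq_len(n)) {
    pr <- simulate_read_pairs(truths[[i]], truths[[i]]$config, locus)
    calls <- emulate_genotype_calls(pr, truths[[i]], sites,
                                    truths[[i]]$config, locus)
    h1[, i] <- calls$h1; h2[, i] <- calls$h2; gt[, i] <- calls$gt
    if (!is.null(pair_fun)) pair_results[[i]] <- pair_fun(pr, truths[[i]])
    if (keep_pairs) pairs_keep[[i]] <- pr
  }
  names(pair_results) <- germ$samples
  called <- phased_callset(sites[, c("chrom", "pos", "ref", "alt")],
                           h1, h2, germ$samples)
  list(config = config, germline = germ, sites = sites, truths = truths,
       called = called, gt = gt, pair_results = pair_results,
       pairs = pairs_keep)
}
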