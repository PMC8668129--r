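# V(D)J signature detectors: insert-size enrichment, interval depth, and
# direct J/V discordant-pair calling, plus the clone profiling built on them.

eligible_pairs <- function(pairs) {
  pairs[!pairs$duplicate & !pairs$secondary, , drop = FALSE]
}

#' Fraction of read pairs with a large insert size
#'
#' V(D)J deletions inflate the reference insert size of fragments spanning
#' the junction; the signature statistic is the fraction of pairs whose
#' outer insert exceeds twice the library insert size (900 bp by default).
#'
#' @param pairs Read-pair `data.frame` (see [simulate_read_pairs()]).
#' @param region `genomic_interval`; a pair is eligible when its leftmost
#'   mate starts inside the region.
#' @param threshold Insert-size threshold in bp.
#' @return A list: `fraction`, `n_large`, `n_eligible`, and `no_data`
#'   (`TRUE`, with `fraction = NA`, when no pair is eligible).
#' @export
fraction_large_inserts <- function(pairs, region, threshold = 900) {
  p <- eligible_pairs(pairs)
  p <- p[p$chrom == region$chrom & p$start1 >= region$start &
           p$start1 < region$end, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(list(fraction = NA_real_, n_large = 0L, n_eligible = 0L,
                no_data = TRUE))
  }
  n_large <- sum(p$insert_size > threshold)
  list(fraction = n_large / nrow(p), n_large = n_large,
       n_eligible = nrow(p), no_data = FALSE)
}

#' Mean read depth over an interval
#'
#' Mean per-base coverage, counting each mate's mapped bases independently.
#'
#' @param pairs Read-pair `data.frame`.
#' @param interval Non-empty `genomic_interval`.
#' @return A list with `interval` and `mean_depth`.
#' @export
mean_depth <- function(pairs, interval) {
  w <- interval_width(interval)
  if (w <= 0) stop("mean_depth() needs a non-empty interval")
  p <- eligible_pairs(pairs)
  p <- p[p$chrom == interval$chrom, , drop = FALSE]
  ov <- function(s, e) {
    pmax(0, pmin(e, interval$end) - pmax(s, interval$start))
  }
  bases <- sum(ov(p$start1, p$end1)) + sum(ov(p$start2, p$end2))
  list(interval = interval, mean_depth = bases / w)
}

# best-overlapping segment per query interval; ties broken by larger
# overlap, then alphabetically first name
best_segment_hit <- function(starts, ends, seg) {
  n <- length(starts)
  res <- rep(NA_character_, n)
  if (nrow(seg) == 0L || n == 0L) return(res)
  hits <- IRanges::findOverlaps(IRanges::IRanges(starts + 1L, ends),
                                IRanges::IRanges(seg$start + 1L, seg$end))
  if (length(hits) == 0L) return(res)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  w <- pmin(ends[q], seg$end[s]) - pmax(starts[q], seg$start[s])
  ord <- order(q, -w, seg$name[s])
  keep <- !duplicated(q[ord])
  res[q[ord][keep]] <- seg$name[s][ord][keep]
  res
}

#' Detect read pairs spanning a V(D)J junction
#'
#' A pair is assigned to an (IGHJ, IGHV) segment pair when exactly one mate
#' overlaps a J segment (by at least 1 bp) and the other overlaps a V
#' segment, both mates mapped on the locus chromosome at `min_mapq` or
#' better.  A mate overlapping several segments of a family is assigned the
#' segment with the larger overlap (alphabetically first name on ties).
#'
#' @param pairs Read-pair `data.frame` (secondary and duplicate records are
#'   ignored).
#' @param locus A `locus_definition`.
#' @param min_mapq Minimum mapping quality for both mates.
#' @return A `data.frame` with one row per assigned pair: `j_name`,
#'   `v_name`.
#' @export
detect_vdj_pairs <- function(pairs, locus, min_mapq = 0L) {
  p <- eligible_pairs(pairs)
  p <- p[p$chrom == locus$chrom & p$mapq1 >= min_mapq & p$mapq2 >= min_mapq, ,
         drop = FALSE]
  empty <- data.frame(j_name = character(), v_name = character(),
                      stringsAsFactors = FALSE)
  if (nrow(p) == 0L) return(empty)
  seg <- locus$segments
  js <- seg[seg$family == "J", , drop = FALSE]
  vs <- seg[seg$family == "V", , drop = FALSE]
  j1 <- best_segment_hit(p$start1, p$end1, js)
  v1 <- best_segment_hit(p$start1, p$end1, vs)
  j2 <- best_segment_hit(p$start2, p$end2, js)
  v2 <- best_segment_hit(p$start2, p$end2, vs)
  fwd <- !is.na(j1) & !is.na(v2) & is.na(v1) & is.na(j2)
  rev <- !is.na(j2) & !is.na(v1) & is.na(v2) & is.na(j1)
  if (!any(fwd | rev)) return(empty)
  data.frame(j_name = c(j1[fwd], j2[rev]), v_name = c(v2[fwd], v1[rev]),
             stringsAsFactors = FALSE)
}

#' Profile the clonality of one sample
#'
#' Groups J/V junction read pairs by segment pair; each unique pair is a
#' clone, its support divided by the total is its frequency, and the
#' max-support pair is the dominant clone whose excised interval is the
#' sample's reported deletion.  Dominant-event ties go to the larger
#' deletion, then to the lexicographically first (J, V) names.
#'
#' @param assignments Output of [detect_vdj_pairs()].
#' @param locus A `locus_definition` whose annotation resolves the segment
#'   names.
#' @param sample_id Sample label carried into the profile.
#' @return A list of class `clonality_profile`.  With zero assignments the
#'   profile has `status = "undetermined"` (distinct from monoclonal).
#' @export
profile_clonality <- function(assignments, locus, sample_id = "sample") {
  if (nrow(assignments) == 0L) {
    return(structure(list(sample_id = sample_id, status = "undetermined",
                          events = data.frame(j_name = character(),
                                              v_name = character(),
                                              support = integer(),
                                              fraction = numeric()),
                          n_clones = 0L, total_support = 0L,
                          dominant_j = NA_character_,
                          dominant_v = NA_character_,
                          dominant_fraction = NA_real_,
                          del_start = NA_real_, del_end = NA_real_,
                          del_size = NA_real_),
                     class = "clonality_profile"))
  }
  tab <- stats::aggregate(list(support = rep(1L, nrow(assignments))),
                          by = assignments[c("j_name", "v_name")], FUN = sum)
  total <- sum(tab$support)
  tab$fraction <- tab$support / total
  seg <- locus$segments
  del_size <- function(j, v) {
    seg$start[match(v, seg$name)] - seg$end[match(j, seg$name)]
  }
  tab$del_size <- del_size(tab$j_name, tab$v_name)
  tab <- tab[order(-tab$support, -tab$del_size, tab$j_name, tab$v_name), ,
             drop = FALSE]
  rownames(tab) <- NULL
  dom <- tab[1, ]
  del <- deletion_interval(seg[match(dom$j_name, seg$name), ],
                           seg[match(dom$v_name, seg$name), ])
  structure(list(sample_id = sample_id, status = "ok",
                 events = tab[c("j_name", "v_name", "support", "fraction")],
                 n_clones = nrow(tab), total_support = total,
                 dominant_j = dom$j_name, dominant_v = dom$v_name,
                 dominant_fraction = dom$fraction,
                 del_start = del$interval$start, del_end = del$interval$end,
                 del_size = del$size),
            class = "clonality_profile")
}

#' Detect and profile in one step
#' @inheritParams detect_vdj_pairs
#' @inheritParams profile_clonality
#' @return A `clonality_profile`.
#' @export
profile_sample <- function(pairs, locus, sample_id = "sample", min_mapq = 0L) {
  profile_clonality(detect_vdj_pairs(pairs, locus, min_mapq), locus,
                    sample_id)
}

#' Flatten clonality profiles to a table
#' @param profiles List of `clonality_profile`s.
#' @return One row per sample with the profile's scalar fields.
#' @export
profiles_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, status = p$status,
               n_clones = p$n_clones, total_support = p$total_support,
               dominant_j = p$dominant_j, dominant_v = p$dominant_v,
               dominant_fraction = p$dominant_fraction,
               del_start = p$del_start, del_end = p$del_end,
               del_size = p$del_size, stringsAsFactors = FALSE)
  }))
}

#' Cohort-level clonality summary
#'
#' @param profiles List of `clonality_profile`s or the table from
#'   [profiles_table()].
#' @return A list: `table` (per-sample), `stats` (mean/range of clone
#'   counts, dominant fractions and deletion sizes; counts of monoclonal
#'   samples and of samples with dominant fraction above 0.5 / 0.75, the
#'   monoclonal samples included in both), and `dominant_matrix` (J-by-V
#'   dominant-clone counts).
#' @export
cohort_summary <- function(profiles) {
  tb <- if (is.data.frame(profiles)) profiles else profiles_table(profiles)
  ok <- tb[tb$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) stop("no determined profiles to summarize")
  rng <- function(x) c(min(x), max(x))
  stats <- data.frame(
    n_samples = nrow(tb),
    n_undetermined = sum(tb$status != "ok"),
    mean_n_clones = mean(ok$n_clones),
    min_n_clones = min(ok$n_clones), max_n_clones = max(ok$n_clones),
    n_monoclonal = sum(ok$n_clones == 1L),
    n_dom_gt50 = sum(ok$dominant_fraction > 0.5),
    n_dom_gt75 = sum(ok$dominant_fraction > 0.75),
    mean_dominant_fraction = mean(ok$dominant_fraction),
    min_dominant_fraction = min(ok$dominant_fraction),
    max_dominant_fraction = max(ok$dominant_fraction),
    mean_del_kb = mean(ok$del_size) / 1e3,
    min_del_kb = min(ok$del_size) / 1e3,
    max_del_kb = max(ok$del_size) / 1e3)
  dominant_matrix <- table(J = ok$dominant_j, V = ok$dominant_v)
  list(table = tb, stats = stats, dominant_matrix = dominant_matrix)
}
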