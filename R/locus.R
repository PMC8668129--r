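# All internal coordinates are 0-based half-open (BED convention).  VCF
# positions are 1-based and converted at the boundary; a 1-based position p
# overlaps interval [start, end) iff start < p <= end.

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open, i.e. `start` is included and `end` is
#' excluded, matching the BED convention used throughout the package.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp); must satisfy `end > start` unless
#'   `allow_empty` is `TRUE`, in which case `end == start` denotes an empty
#'   interval.
#' @param allow_empty Permit zero-width intervals.
#' @return A list of class `genomic_interval` with fields `chrom`, `start`,
#'   `end`.
#' @export
genomic_interval <- function(chrom, start, end, allow_empty = FALSE) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            is.numeric(start), is.numeric(end),
            length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (start < 0) stop("interval start must be >= 0")
  if (allow_empty) {
    if (end < start) stop("interval end must be >= start")
  } else if (end <= start) {
    stop("interval end must be > start")
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' Width of a genomic interval in bp
#' @param x A `genomic_interval`.
#' @return Numeric width (`end - start`).
#' @export
interval_width <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(interval_width(x), big.mark = ",")))
  invisible(x)
}

# segment family from an IGH gene name prefix; errors on unknown prefixes
segment_family <- function(name) {
  fam <- rep(NA_character_, length(name))
  fam[startsWith(name, "IGHV")] <- "V"
  fam[startsWith(name, "IGHD")] <- "D"
  fam[startsWith(name, "IGHJ")] <- "J"
  if (anyNA(fam)) {
    bad <- name[is.na(fam)]
    stop("cannot parse gene-segment family from name(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  fam
}

#' Build a gene-segment table
#'
#' @param name Segment names (`IGHV*`, `IGHD*`, `IGHJ*`); the family is
#'   parsed from the prefix.
#' @param chrom,start,end Interval columns, 0-based half-open.
#' @param strand Strand; IGH gene segments sit on the minus strand in GRCh38.
#' @param score Optional BED score column.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `family`, ordered by coordinate.
#' @export
gene_segments <- function(name, chrom, start, end, strand = "-", score = 0L) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  if (length(name) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(), score = integer(),
                      strand = character(), family = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(end <= start)) stop("gene segment with start >= end")
  if (any(start < 0)) stop("gene segment with negative start")
  seg <- data.frame(chrom = chrom, start = as.numeric(start),
                    end = as.numeric(end), name = name,
                    score = score, strand = strand,
                    family = segment_family(name),
                    stringsAsFactors = FALSE)
  seg[order(seg$chrom, seg$start, seg$end), , drop = FALSE]
}

#' Read a gene-segment annotation from BED6
#'
#' Expects a 6-column BED (chrom, start, end, name, score, strand), 0-based
#' half-open, with names carrying the IGHV/IGHD/IGHJ family prefix.
#'
#' @param path Path to a BED file.
#' @return A gene-segment `data.frame` (see [gene_segments()]); empty files
#'   yield a zero-row table.
#' @export
load_segments <- function(path) {
  if (!file.exists(path)) stop("segment BED not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) {
                   stop("malformed BED '", path, "': ", conditionMessage(e))
                 })
  if (length(gr) == 0L) {
    return(gene_segments(character(), character(), numeric(), numeric()))
  }
  if (is.null(gr$name) || anyNA(gr$name)) {
    stop("BED '", path, "' is missing the name column required for segments")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "-"
  score <- if (is.null(gr$score)) 0L else ifelse(is.na(gr$score), 0L, gr$score)
  gene_segments(name = gr$name,
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = BiocGenerics::start(gr) - 1L,
                end = BiocGenerics::end(gr),
                strand = strand, score = score)
}

#' Write a gene-segment table as BED6
#' @param segments A gene-segment `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  df <- segments[order(segments$chrom, segments$start, segments$end), ]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), df$name, as.integer(df$score),
                   df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Assemble and validate an IGH locus definition
#'
#' The locus model keys all interval logic: the reference-coordinate order of
#' the regions is J < D < V, and the V region starts at the 3' end of IGHV6-1
#' (on the minus strand the 3' end of a V segment is its lowest reference
#' coordinate).
#'
#' @param chrom Chromosome name.
#' @param locus,j_region,d_region,v_region `genomic_interval`s.
#' @param segments Gene-segment `data.frame`; every segment must lie inside
#'   `locus`.
#' @return A list of class `locus_definition`.
#' @export
locus_definition <- function(chrom, locus, j_region, d_region, v_region,
                             segments) {
  stopifnot(inherits(locus, "genomic_interval"))
  if (!(j_region$end <= d_region$start && d_region$start <= d_region$end &&
        d_region$end <= v_region$start)) {
    stop("region order violated: need j_region <= d_region <= v_region")
  }
  if (nrow(segments) > 0) {
    inside <- segments$chrom == chrom & segments$start >= locus$start &
      segments$end <= locus$end
    if (!all(inside)) {
      stop("segments outside the locus span: ",
           paste(segments$name[!inside], collapse = ", "))
    }
  }
  structure(list(chrom = chrom, locus = locus, j_region = j_region,
                 d_region = d_region, v_region = v_region,
                 segments = segments),
            class = "locus_definition")
}

# GRCh38 IGH landmarks (bp).  The locus spans chr14:105862198-107043718; the
# D region is chr14:105,865,458-105,939,756 and the V region starts at the 3'
# end of IGHV6-1 (105,939,756) and runs to 106,883,718.
IGH_CHROM <- "chr14"
IGH_LOCUS_START <- 105862198
IGH_LOCUS_END <- 107043718
IGH_D_START <- 105865458
IGH_V_START <- 105939756
IGH_V_END <- 106883718

#' The GRCh38 IGH locus definition
#'
#' Landmark coordinates are the published GRCh38 region boundaries; the
#' gene-segment annotation defaults to the bundled synthetic fixture (see
#' [igh_segments_synthetic()]), which places plausible segments inside those
#' boundaries.  Real analyses should pass their own annotation BED.
#'
#' @param segments Optional gene-segment `data.frame` replacing the bundled
#'   synthetic annotation.
#' @return A `locus_definition`.
#' @export
igh_locus <- function(segments = NULL) {
  if (is.null(segments)) segments <- igh_segments_synthetic()
  locus_definition(
    chrom = IGH_CHROM,
    locus = genomic_interval(IGH_CHROM, IGH_LOCUS_START, IGH_LOCUS_END),
    j_region = genomic_interval(IGH_CHROM, IGH_LOCUS_START, IGH_D_START),
    d_region = genomic_interval(IGH_CHROM, IGH_D_START, IGH_V_START),
    v_region = genomic_interval(IGH_CHROM, IGH_V_START, IGH_V_END),
    segments = segments
  )
}

#' Bundled synthetic IGH gene-segment annotation
#'
#' A synthetic, hg38-plausible annotation of 6 IGHJ, 27 IGHD and 50 IGHV
#' segments inside the published IGH span, shipped so simulations and tests
#' run without any download.  IGHJ1 ends exactly at the IGHD-region boundary
#' (chr14:105,865,458) and IGHV6-1 starts exactly at the V-region boundary
#' (chr14:105,939,756), so the minimal J-V join spans the published D region.
#' Per-gene coordinates other than those landmarks are invented; do not use
#' this table to interpret real alignments.
#'
#' @return A gene-segment `data.frame`.
#' @export
igh_segments_synthetic <- function() {
  path <- system.file("extdata", "igh_segments_synthetic.bed",
                      package = "igclone", mustWork = TRUE)
  load_segments(path)
}

#' Excised interval implied by a J-V join
#'
#' V(D)J recombination excises the DNA between the selected IGHJ and IGHV
#' gene segments.  The deletion is measured from the J segment's reference
#' end to the V segment's reference start (its 3' end on the minus strand):
#' the span of intervening DNA lost on the recombined chromosome.
#'
#' @param j,v Single-row gene-segment `data.frame`s (families J and V).
#' @return A list with `interval` (a `genomic_interval`, possibly empty) and
#'   `size` in bp.
#' @export
deletion_interval <- function(j, v) {
  j <- as.list(j[1, , drop = FALSE]); v <- as.list(v[1, , drop = FALSE])
  if (!identical(j$family, "J") || !identical(v$family, "V")) {
    stop("deletion_interval() needs a J segment and a V segment")
  }
  if (!identical(j$chrom, v$chrom)) stop("J and V segments on different chromosomes")
  if (j$end > v$start) stop("J segment must precede the V segment")
  list(interval = genomic_interval(j$chrom, j$end, v$start, allow_empty = TRUE),
       size = v$start - j$end)
}

#' Write per-sample deletion intervals as BED
#'
#' One line per sample: the excised interval of the dominant clone, with the
#' name column `sample|Jname|Vname`.  Round-trips losslessly through
#' [read_deletion_bed()].
#'
#' @param records `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `end`, `j_name`, `v_name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deletion_bed <- function(records, path) {
  need <- c("sample_id", "chrom", "start", "end", "j_name", "v_name")
  if (!all(need %in% names(records))) {
    stop("deletion records need columns: ", paste(need, collapse = ", "))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t-", records$chrom,
                   as.integer(records$start), as.integer(records$end),
                   paste(records$sample_id, records$j_name, records$v_name,
                         sep = "|"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample deletion BED written by [write_deletion_bed()]
#' @param path Path to the BED file.
#' @return A `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `j_name`, `v_name`.
#' @export
read_deletion_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      j_name = character(), v_name = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 4L)
  if (length(bad)) stop("malformed deletion BED line ", bad[1], " in ", path)
  name <- strsplit(vapply(f, `[[`, "", 4L), "|", fixed = TRUE)
  if (any(lengths(name) != 3L)) {
    stop("deletion BED name column must be sample|J|V in ", path)
  }
  starts <- as.numeric(vapply(f, `[[`, "", 2L))
  ends <- as.numeric(vapply(f, `[[`, "", 3L))
  if (anyNA(starts) || anyNA(ends) || any(ends < starts)) {
    stop("malformed coordinates in deletion BED ", path)
  }
  data.frame(sample_id = vapply(name, `[[`, "", 1L),
             chrom = vapply(f, `[[`, "", 1L),
             start = starts, end = ends,
             j_name = vapply(name, `[[`, "", 2L),
             v_name = vapply(name, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Read a locus definition from a key-value config file
#'
#' Flat `key = value` lines: `chrom`, `locus_start`, `locus_end`,
#' `j_start`, `j_end`, `d_start`, `d_end`, `v_start`, `v_end`, and
#' optionally `segments` (path to a BED, resolved relative to the config
#' file).
#'
#' @param path Config file path.
#' @param segments Optional segment table overriding the config's BED.
#' @return A `locus_definition`.
#' @export
read_locus_config <- function(path, segments = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("locus config missing key: ", k)
    vals[i]
  }
  num <- function(k) as.numeric(get(k))
  chrom <- get("chrom")
  if (is.null(segments)) {
    i <- match("segments", keys)
    if (is.na(i)) stop("locus config needs a segments BED or an explicit table")
    bed <- vals[i]
    if (!file.exists(bed)) bed <- file.path(dirname(path), vals[i])
    segments <- load_segments(bed)
  }
  locus_definition(
    chrom = chrom,
    locus = genomic_interval(chrom, num("locus_start"), num("locus_end")),
    j_region = genomic_interval(chrom, num("j_start"), num("j_end")),
    d_region = genomic_interval(chrom, num("d_start"), num("d_end")),
    v_region = genomic_interval(chrom, num("v_start"), num("v_end")),
    segments = segments)
}
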