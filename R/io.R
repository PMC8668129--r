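# Alignment, VCF and truth-table I/O for the simulator's outputs.  SAM is
# written as text and read back through Rsamtools (SAM -> BAM -> records);
# VCF is written as text and parsed with vcfR.

sam_flag <- function(mate, proper, duplicate, secondary) {
  base <- 1L + ifelse(proper, 2L, 0L) + ifelse(duplicate, 1024L, 0L) +
    ifelse(secondary, 256L, 0L)
  if (mate == 1L) base + 64L + 32L else base + 128L + 16L
}

sam_cigar <- function(width, clip, read_length) {
  s <- read_length - width
  ifelse(s == 0L, paste0(width, "M"),
         ifelse(clip == "right", paste0(width, "M", s, "S"),
                paste0(s, "S", width, "M")))
}

#' Write read pairs as SAM
#'
#' Emits a minimal coordinate-sorted SAM: header with the locus chromosome,
#' one record per mate with FLAG/POS/MAPQ/CIGAR/PNEXT/TLEN.  Junction-
#' clipped reads carry soft-clip CIGAR operations; sequences are omitted
#' (`*`).
#'
#' @param pairs Read-pair `data.frame` from [simulate_read_pairs()].
#' @param path Output path (`.sam`).
#' @param locus A `locus_definition` (names the reference sequence).
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, path, locus) {
  rl <- if (nrow(pairs)) {
    max(pairs$end1 - pairs$start1, pairs$end2 - pairs$start2)
  } else 150L
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", locus$chrom,
                      as.integer(locus$locus$end + 1000L)))
  if (nrow(pairs) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  w1 <- as.integer(pairs$end1 - pairs$start1)
  w2 <- as.integer(pairs$end2 - pairs$start2)
  rec <- function(mate) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
            pairs$qname,
            sam_flag(mate, pairs$proper, pairs$duplicate, pairs$secondary),
            pairs$chrom,
            as.integer(if (mate == 1L) pairs$start1 else pairs$start2) + 1L,
            as.integer(if (mate == 1L) pairs$mapq1 else pairs$mapq2),
            sam_cigar(if (mate == 1L) w1 else w2,
                      if (mate == 1L) pairs$clip1 else pairs$clip2, rl),
            as.integer(if (mate == 1L) pairs$start2 else pairs$start1) + 1L,
            as.integer(if (mate == 1L) pairs$insert_size
                       else -pairs$insert_size))
  }
  records <- c(rec(1L), rec(2L))
  ord <- order(c(pairs$start1, pairs$start2))
  writeLines(c(header, records[ord]), path)
  invisible(path)
}

cigar_ref_width <- function(cigar) {
  # reference-consuming ops only (M/D/N/=/X); the simulator emits M and S
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    parts <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]", "", parts[grepl("[MDN=X]$", parts)])))
  }, 0L, USE.NAMES = FALSE)
}

#' Read a SAM file back into read pairs
#'
#' @param path SAM path (converted to BAM internally).
#' @param sample_id Sample label to attach.
#' @return A read-pair `data.frame` with the same core columns written by
#'   [write_sam()] (simulation provenance columns are not recoverable).
#' @export
read_sam <- function(path, sample_id = "sample") {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "isize")))[[1]]
  w <- cigar_ref_width(res$cigar)
  clip_of <- function(cigar) {
    ifelse(grepl("S$", cigar), "right",
           ifelse(grepl("^\\d+S", cigar), "left", "none"))
  }
  df <- data.frame(qname = res$qname, flag = res$flag,
                   chrom = as.character(res$rname),
                   start = res$pos - 1L, end = res$pos - 1L + w,
                   clip = clip_of(res$cigar),
                   mapq = res$mapq, isize = res$isize,
                   stringsAsFactors = FALSE)
  first <- df[bitwAnd(df$flag, 64L) > 0L, ]
  second <- df[bitwAnd(df$flag, 128L) > 0L, ]
  m <- match(first$qname, second$qname)
  if (anyNA(m)) stop("unpaired records in ", path)
  second <- second[m, ]
  pairs <- data.frame(
    sample_id = sample_id, chrom = first$chrom,
    start1 = first$start, end1 = first$end, clip1 = first$clip,
    start2 = second$start, end2 = second$end, clip2 = second$clip,
    mapq1 = first$mapq, mapq2 = second$mapq,
    insert_size = abs(first$isize),
    proper = bitwAnd(first$flag, 2L) > 0L,
    duplicate = bitwAnd(first$flag, 1024L) > 0L,
    secondary = bitwAnd(first$flag, 256L) > 0L,
    qname = first$qname,
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$start1, pairs$start2), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Write a phased call set as VCF 4.2
#'
#' Biallelic SNPs, one phased sample column per sample (`0|1` style;
#' missing as `.|.`).
#'
#' @param callset A `phased_callset`.
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path) {
  s <- callset$sites
  gt <- matrix(paste(callset$h1, callset$h2, sep = "|"),
               nrow = nrow(s))
  gt[is.na(callset$h1) | is.na(callset$h2)] <- ".|."
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(s$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", callset$samples), collapse = "\t"))
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a call set
#'
#' Restricted to biallelic SNPs; genotype separators `|` (phased) or `/`
#' (unphased — the callset is then flagged unphased and unusable for LD).
#'
#' @param path VCF path.
#' @return A `phased_callset`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  fix <- fix[snp, , drop = FALSE]; gt <- gt[snp, , drop = FALSE]
  phased <- !any(grepl("/", gt, fixed = TRUE), na.rm = TRUE)
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  h1 <- matrix(a1, nrow = nrow(fix)); h2 <- matrix(a2, nrow = nrow(fix))
  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  phased_callset(sites, h1, h2, colnames(gt), phased = phased)
}

#' Write simulation ground truth
#'
#' One TSV row per clone (`sample`, `clone`, `fraction`, `j`, `v`,
#' `deletion_start`, `deletion_end`) plus a dominant-deletion BED in the
#' [write_deletion_bed()] format.
#'
#' @param truths List of `sim_truth` objects.
#' @param tsv_path,bed_path Output paths.
#' @param chrom Chromosome written in the BED.
#' @return Invisibly, the truth `data.frame`.
#' @export
write_truth <- function(truths, tsv_path, bed_path, chrom = "chr14") {
  tab <- do.call(rbind, lapply(truths, function(t) {
    data.frame(sample = t$sample_id, clone = t$clones$clone_id,
               fraction = t$clones$fraction, j = t$clones$j_name,
               v = t$clones$v_name, deletion_start = t$clones$del1_start,
               deletion_end = t$clones$del1_end, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dom <- do.call(rbind, lapply(truths, function(t) {
    if (is.na(t$deletion[1])) return(NULL)
    data.frame(sample_id = t$sample_id, chrom = chrom,
               start = t$deletion[1], end = t$deletion[2],
               j_name = t$dominant_j, v_name = t$dominant_v,
               stringsAsFactors = FALSE)
  }))
  if (is.null(dom)) writeLines(character(), bed_path)
  else write_deletion_bed(dom, bed_path)
  invisible(tab)
}
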