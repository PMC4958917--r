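# Candidate-read extraction: reads mapped to the TCRB locus window plus all
# unmapped reads, pulled from a coordinate-sorted, indexed BAM. Secondary,
# supplementary and duplicate-flagged records are excluded everywhere;
# reverse-strand alignments are emitted as the original read sequence.

#' Total soft+hard clipped bases of CIGAR strings
#' @noRd
cigar_clip_bases <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    m <- regmatches(cg, gregexpr("[0-9]+[SH]", cg))[[1]]
    if (!length(m)) return(0L)
    sum(as.integer(sub("[SH]", "", m)))
  }, 0L, USE.NAMES = FALSE)
}

#' @noRd
check_bam_window <- function(bam, window) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  idx <- paste0(bam, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam)
  if (!file.exists(idx) && !file.exists(idx2)) {
    stop("missing BAM index for ", bam, " (run samtools index / indexBam)")
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!window$chrom %in% names(targets)) {
    stop("window contig '", window$chrom, "' absent from BAM header")
  }
  invisible(targets)
}

#' Suffix paired-read names with the mate index
#' @noRd
mate_qname <- function(qname, flag) {
  paired <- bitwAnd(flag, 0x1) > 0L
  first <- bitwAnd(flag, 0x40) > 0L
  ifelse(paired, paste0(qname, ifelse(first, "/1", "/2")), qname)
}

#' Extract candidate CDR3-bearing reads from a BAM
#'
#' Collects every primary, non-duplicate record whose alignment overlaps the
#' TCRB window by at least one base, plus every primary unmapped record.
#' Reverse-strand alignments are reverse-complemented back to the original
#' read sequence. `total_reads` counts the primary records of the whole file
#' and is the denominator of the CDR3 reads-per-million normalization.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param window TCRB locus interval (list or `"chrom:start-end"` string);
#'   defaults to [tcrb_locus_window()].
#' @param sample_id Sample label; defaults to the BAM basename.
#' @param denominator `"primary-nodup"` (default; primary records not
#'   flagged duplicate, matching an upstream MarkDuplicates step) or
#'   `"primary"` (all primary records).
#' @return An object of class `CandidateReadSet`: list with `sample_id`,
#'   `reads` (data.frame: read_id, seq, source in {locus_mapped, unmapped},
#'   clipped) and `total_reads`.
#' @export
harvest <- function(bam, window = tcrb_locus_window(), sample_id = NULL,
                    denominator = c("primary-nodup", "primary")) {
  window <- as_window(window)
  denominator <- match.arg(denominator)
  check_bam_window(bam, window)
  if (is.null(sample_id)) sample_id <- sub("\\.bam$", "", basename(bam))

  what <- c("qname", "flag", "strand", "seq", "cigar")
  gr <- GenomicRanges::GRanges(
    window$chrom, IRanges::IRanges(window$start, window$end)
  )
  mapped <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    which = gr, what = what,
    flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE, isUnmappedQuery = FALSE
    )
  ))[[1]]
  unmapped <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = what,
    flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE, isUnmappedQuery = TRUE
    )
  ))[[1]]

  build <- function(x, source) {
    n <- length(x$qname)
    if (n == 0L) {
      return(data.frame(
        read_id = character(0), seq = character(0), source = character(0),
        clipped = logical(0), stringsAsFactors = FALSE
      ))
    }
    sq <- as.character(x$seq)
    rev <- !is.na(x$strand) & x$strand == "-"
    if (any(rev)) sq[rev] <- revcomp(sq[rev])
    data.frame(
      read_id = mate_qname(x$qname, x$flag),
      seq = sq,
      source = source,
      clipped = cigar_clip_bases(x$cigar) > 0L,
      stringsAsFactors = FALSE
    )
  }
  reads <- rbind(build(mapped, "locus_mapped"), build(unmapped, "unmapped"))
  reads <- reads[order(reads$read_id), , drop = FALSE]
  reads <- reads[!duplicated(reads$read_id), , drop = FALSE]
  rownames(reads) <- NULL

  dupflag <- if (denominator == "primary-nodup") FALSE else NA
  total <- Rsamtools::countBam(bam, param = Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = dupflag
    )
  ))$records

  structure(
    list(sample_id = sample_id, reads = reads, total_reads = total),
    class = "CandidateReadSet"
  )
}

#' @export
print.CandidateReadSet <- function(x, ...) {
  cat(sprintf(
    "CandidateReadSet '%s': %d candidate reads (%d locus-mapped, %d unmapped) of %s total\n",
    x$sample_id, nrow(x$reads), sum(x$reads$source == "locus_mapped"),
    sum(x$reads$source == "unmapped"), format(x$total_reads, big.mark = ",")
  ))
  invisible(x)
}

#' Fraction of clipped reads in the TCRB window
#'
#' Among primary, non-duplicate reads overlapping the window, the fraction
#' whose CIGAR carries at least `min_clip` soft- or hard-clipped bases —
#' the expected signature of rearranged reads forced onto the unrearranged
#' germline locus.
#'
#' @inheritParams harvest
#' @param min_clip Minimum clipped bases for a read to count as clipped.
#' @return A fraction in \[0, 1\]; 0 with a warning on an empty window.
#' @export
clipped_fraction <- function(bam, window = tcrb_locus_window(), min_clip = 10L) {
  window <- as_window(window)
  check_bam_window(bam, window)
  gr <- GenomicRanges::GRanges(
    window$chrom, IRanges::IRanges(window$start, window$end)
  )
  x <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    which = gr, what = c("cigar"),
    flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE, isUnmappedQuery = FALSE
    )
  ))[[1]]
  n <- length(x$cigar)
  if (n == 0L) {
    warning("no primary reads overlap the window; returning 0")
    return(0)
  }
  sum(cigar_clip_bases(x$cigar) >= min_clip) / n
}

#' Write a candidate read set as FASTQ
#'
#' One record per candidate read, constant quality, ids preserved.
#'
#' @param set A `CandidateReadSet`.
#' @param out Output FASTQ path.
#' @return The number of records written.
#' @export
to_fastq <- function(set, out) {
  reads <- set$reads
  if (nrow(reads) == 0L) {
    writeLines(character(0), out)
    return(0L)
  }
  writeLines(
    as.vector(rbind(
      paste0("@", reads$read_id), reads$seq, "+",
      vapply(nchar(reads$seq), function(n) strrep("I", n), "")
    )),
    out
  )
  nrow(reads)
}

#' Build a candidate read set from a FASTQ file
#'
#' For running the detector on reads already extracted to FASTQ (the
#' harvest-then-detect workflow); the total primary read count of the
#' originating BAM must be supplied for RPM normalization.
#'
#' @param fastq Path to a FASTQ file.
#' @param total_reads Total primary reads sequenced for the sample.
#' @param sample_id Sample label; defaults to the FASTQ basename.
#' @return A `CandidateReadSet` (source marked `"fastq"`).
#' @export
candidate_set_from_fastq <- function(fastq, total_reads, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  }
  sq <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  reads <- data.frame(
    read_id = sub("\\s.*$", "", names(sq)),
    seq = as.character(sq),
    source = rep("fastq", length(sq)),
    clipped = rep(NA, length(sq)),
    stringsAsFactors = FALSE
  )
  structure(
    list(sample_id = sample_id, reads = reads, total_reads = total_reads),
    class = "CandidateReadSet"
  )
}
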