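# Shared fixtures: a small hand-built reference whose coordinates are easy
# to reason about, a SAM->BAM builder for harvest tests, and an exhaustive
# ungapped Smith-Waterman oracle for the aligner.

# V: 27 nt upstream context + TGT anchor + 3 nt tail (anchor_offset 27)
# J: 6 nt 5' region + TTTGGCGGCGGA motif + 8 nt tail (anchor_offset 6)
fixed_reference <- function() {
  v1 <- paste0("ACCTGACTGGAACGTCTTGGAACCTGA", "TGT", "CCA")
  v2 <- paste0("GGTACCATTGCACGTTGGCAATCCGTA", "TGC", "GAA")
  j1 <- paste0("CAACTC", "TTTGGCGGCGGA", "ACCTTGGA")
  j2 <- paste0("GGATTG", "TTCGGTTCAGGG", "TCACTTCA")
  reference_set(list(
    germline_segment("TRBV-A", "V", v1, 27),
    germline_segment("TRBV-B", "V", v2, 27),
    germline_segment("TRBJ-A", "J", j1, 6),
    germline_segment("TRBJ-B", "J", j2, 6)
  ))
}

# A read carrying a clean junction: full V + insert + full J
junction_read <- function(ref = fixed_reference(), v = "TRBV-A", j = "TRBJ-A",
                          insert = "GCCAGCAGC", v_trim = 3, j_trim = 6) {
  r <- rearrange(rearrangement_spec(v, j, v_trim, j_trim, insert), ref)
  r
}

# Build an indexed BAM from a record table. Records: data.frame with
# qname, flag, rname, pos, mapq, cigar, seq (qual auto-generated).
make_test_bam <- function(records, path,
                          contigs = c(chrT = 100000L)) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs)
  )
  qual <- vapply(nchar(records$seq), function(n) strrep("I", n), "")
  lines <- paste(
    records$qname, records$flag, records$rname, records$pos, records$mapq,
    records$cigar, "*", 0L, 0L, records$seq, qual,
    sep = "\t"
  )
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, lines), sam)
  out <- sam_to_bam(sam, path)
  unlink(sam)
  out
}

sam_record <- function(qname, flag = 0L, rname = "chrT", pos = 1L,
                       mapq = 60L, cigar = NULL, seq = NULL) {
  if (is.null(seq)) seq <- strrep("ACGT", 10)
  if (is.null(cigar)) cigar <- if (bitwAnd(flag, 4L) > 0L) "*" else paste0(nchar(seq), "M")
  if (bitwAnd(flag, 4L) > 0L) { rname <- "*"; pos <- 0L; mapq <- 0L }
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

# Exhaustive ungapped Smith-Waterman (+1 match / -1 mismatch), independent
# of the package's seed-and-extend path: enumerates every diagonal and
# every sub-interval meeting the length and mismatch constraints.
oracle_best_ungapped <- function(read, seg, min_len, max_mm) {
  rl <- nchar(read); sl <- nchar(seg)
  rc <- strsplit(read, "")[[1]]
  sc <- strsplit(seg, "")[[1]]
  best <- NULL
  for (d in (1L - rl):(sl - 1L)) {
    lo <- max(1L, 1L - d); hi <- min(rl, sl - d)
    if (hi - lo + 1L < min_len) next
    m <- rc[lo:hi] == sc[(lo + d):(hi + d)]
    n <- length(m)
    cmm <- cumsum(!m)
    for (i in seq_len(n)) {
      for (j in i:n) {
        len <- j - i + 1L
        if (len < min_len) next
        mm <- cmm[j] - if (i > 1L) cmm[i - 1L] else 0L
        if (mm / len > max_mm) next
        s <- (len - mm) - mm
        if (is.null(best) || s > best) best <- s
      }
    }
  }
  best
}

# Independent enumeration of template start positions whose read fully
# spans the CDR3 and keeps the caller's minimum V/J flanks.
enumerate_detectable_reads <- function(rearr, read_length,
                                       min_v = 20L, min_j = 12L,
                                       pad_left = NULL, pad_right = NULL) {
  lf <- nchar(rearr$full_nt)
  if (is.null(pad_left)) pad_left <- strrep("T", read_length - 1L)
  if (is.null(pad_right)) pad_right <- strrep("A", read_length - 1L)
  ext <- paste0(pad_left, rearr$full_nt, pad_right)
  out <- character(0)
  for (s in (2L - read_length):lf) {
    e <- s + read_length - 1L
    spans <- s <= rearr$cdr3_start && e >= rearr$cdr3_end
    v_aligned <- max(0L, min(e, rearr$v_kept) - max(s, 1L) + 1L)
    j_aligned <- max(0L, min(e, lf) - max(s, rearr$j_start) + 1L)
    if (spans && v_aligned >= min_v && j_aligned >= min_j) {
      off <- s + read_length - 1L   # position within ext
      out <- c(out, substr(ext, off, off + read_length - 1L))
    }
  }
  out
}
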