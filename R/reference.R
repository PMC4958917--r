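# Germline TCRB V/J segment references with conserved-anchor annotations.
#
# The CDR3 of a rearranged TCRB gene is delimited by two conserved codons:
# the cysteine near the 3' end of the V segment and the phenylalanine (or
# tryptophan) of the [FW]-G-x-G motif near the 5' end of the J segment.
# Detection of rearranged reads is anchored on these codons, so every V/J
# segment carries a 0-based `anchor_offset` locating the first base of its
# anchor codon, validated against the motif at load time.

#' Default TCRB locus window (hg19)
#'
#' The genomic interval of the human TCRB locus used to harvest candidate
#' reads, 1-based inclusive.
#'
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
#' @examples
#' tcrb_locus_window()
tcrb_locus_window <- function() {
  list(chrom = "chr7", start = 142000817, end = 142510993)
}

#' Construct a germline V, D or J segment
#'
#' @param id Segment name (unique within a reference set).
#' @param class One of `"V"`, `"J"`, `"D"`.
#' @param seq Nucleotide string over A/C/G/T.
#' @param anchor_offset 0-based offset of the first base of the conserved
#'   anchor codon (V: cysteine; J: phenylalanine/tryptophan of the
#'   \[FW\]GxG motif). Required for V and J, `NA` for D.
#' @return An object of class `GermlineSegment`.
#' @export
germline_segment <- function(id, class, seq, anchor_offset = NA_integer_) {
  seg <- structure(
    list(
      id = as.character(id), class = match.arg(class, c("V", "J", "D")),
      seq = toupper(as.character(seq)),
      anchor_offset = if (is.na(anchor_offset)) NA_integer_ else as.integer(anchor_offset)
    ),
    class = "GermlineSegment"
  )
  validate_segment(seg)
  seg
}

#' Validate a germline segment's anchor invariants
#'
#' Checks that the sequence is non-empty A/C/G/T, that V anchors translate to
#' cysteine, and that J anchors start an \[FW\]-G-x-G motif (glycines at
#' codon positions 2 and 4).
#'
#' @param seg A `GermlineSegment`.
#' @return The segment, invisibly; errors describe the offending codon.
#' @export
validate_segment <- function(seg) {
  if (!nzchar(seg$seq)) stop("segment '", seg$id, "': empty sequence")
  if (grepl("[^ACGT]", seg$seq)) {
    stop("segment '", seg$id, "': sequence contains non-ACGT characters")
  }
  if (seg$class == "D") {
    return(invisible(seg))
  }
  off <- seg$anchor_offset
  if (is.na(off)) stop("segment '", seg$id, "': missing anchor_offset for class ", seg$class)
  if (off < 0L || off + 3L > nchar(seg$seq)) {
    stop("segment '", seg$id, "': anchor_offset out of range")
  }
  codon <- substr(seg$seq, off + 1L, off + 3L)
  aa <- translate_nt(codon)
  if (seg$class == "V") {
    if (aa != "C") {
      stop("segment '", seg$id, "': anchor is not cysteine (codon ", codon, " -> ", aa, ")")
    }
  } else {
    if (!aa %in% c("F", "W")) {
      stop("segment '", seg$id, "': J anchor is not phenylalanine/tryptophan (codon ",
           codon, " -> ", aa, ")")
    }
    if (off + 12L > nchar(seg$seq)) {
      stop("segment '", seg$id, "': J segment too short for the [FW]GxG motif")
    }
    motif_aa <- translate_nt(substr(seg$seq, off + 1L, off + 12L))
    if (substr(motif_aa, 2L, 2L) != "G" || substr(motif_aa, 4L, 4L) != "G") {
      stop("segment '", seg$id, "': bases after the J anchor do not match the ",
           "[FW]GxG motif (", motif_aa, ")")
    }
  }
  invisible(seg)
}

#' Construct a validated reference set
#'
#' @param segments A list of `GermlineSegment` objects.
#' @param locus_window Genomic interval of the TCRB locus (list or
#'   `"chrom:start-end"` string); defaults to [tcrb_locus_window()].
#' @return An object of class `ReferenceSet` with elements `segments`
#'   (a data.frame with columns id, class, seq, anchor_offset) and
#'   `locus_window`.
#' @export
reference_set <- function(segments, locus_window = tcrb_locus_window()) {
  stopifnot(length(segments) >= 1L)
  segs <- do.call(rbind, lapply(segments, function(s) {
    validate_segment(s)
    data.frame(
      id = s$id, class = s$class, seq = s$seq,
      anchor_offset = s$anchor_offset, stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(segs$id)) {
    stop("duplicate segment ids: ", paste(unique(segs$id[duplicated(segs$id)]), collapse = ", "))
  }
  if (!any(segs$class == "V") || !any(segs$class == "J")) {
    stop("reference set needs at least one V and one J segment")
  }
  structure(
    list(segments = segs, locus_window = as_window(locus_window)),
    class = "ReferenceSet"
  )
}

#' @export
print.ReferenceSet <- function(x, ...) {
  tab <- table(x$segments$class)
  cat("ReferenceSet:", paste(names(tab), tab, sep = "=", collapse = " "),
      sprintf("| locus %s:%s-%s\n", x$locus_window$chrom,
              format(x$locus_window$start, big.mark = ","),
              format(x$locus_window$end, big.mark = ",")))
  invisible(x)
}

#' Fetch one segment of a reference set as a GermlineSegment
#' @noRd
get_segment <- function(ref, id) {
  i <- match(id, ref$segments$id)
  if (is.na(i)) stop("segment '", id, "' not found in reference")
  r <- ref$segments[i, ]
  structure(
    list(id = r$id, class = r$class, seq = r$seq, anchor_offset = r$anchor_offset),
    class = "GermlineSegment"
  )
}

#' Read a germline reference from FASTA plus an anchor table
#'
#' The anchor table is a 3-column TSV with header `id  class  anchor_offset`
#' (0-based offsets; D segments may leave the offset empty/NA). Every V and J
#' sequence in the FASTA must have an anchor row and pass the conserved-motif
#' checks.
#'
#' @param fasta_path Path to the segment FASTA.
#' @param anchors_path Path to the anchor TSV.
#' @param locus_window Locus interval, defaulting to [tcrb_locus_window()].
#' @return A `ReferenceSet`.
#' @export
read_reference <- function(fasta_path, anchors_path, locus_window = tcrb_locus_window()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  anchors <- utils::read.delim(anchors_path, stringsAsFactors = FALSE)
  required <- c("id", "class", "anchor_offset")
  if (!all(required %in% names(anchors))) {
    stop("anchor table must have columns: ", paste(required, collapse = ", "))
  }
  extra <- setdiff(anchors$id, ids)
  if (length(extra)) {
    stop("anchor table rows without a FASTA sequence: ", paste(extra, collapse = ", "))
  }
  segments <- lapply(seq_along(ids), function(i) {
    row <- anchors[match(ids[i], anchors$id), ]
    if (is.na(row$id)) {
      stop("missing anchor row for segment '", ids[i], "'")
    }
    germline_segment(ids[i], row$class, as.character(seqs[[i]]), row$anchor_offset)
  })
  reference_set(segments, locus_window)
}

#' Write a reference set to FASTA plus an anchor table
#'
#' Round-trips with [read_reference()].
#'
#' @param ref A `ReferenceSet`.
#' @param fasta_path,anchors_path Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_reference <- function(ref, fasta_path, anchors_path) {
  segs <- ref$segments
  writeLines(
    as.vector(rbind(paste0(">", segs$id), segs$seq)),
    fasta_path
  )
  utils::write.table(
    segs[, c("id", "class", "anchor_offset")],
    anchors_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(fasta = fasta_path, anchors = anchors_path))
}

#' Split a V or J segment at its conserved anchor codon
#'
#' For V segments the upstream part runs up to and including the anchor
#' codon; for J segments the downstream part starts at the anchor codon.
#' Concatenating the two parts reconstructs the input sequence.
#'
#' @param segment A `GermlineSegment` (V or J).
#' @return A list with `upstream` and `downstream` nucleotide strings.
#' @export
#' @examples
#' v <- germline_segment("V1", "V", "AATGTCC", 2)
#' split_on_anchor(v) # upstream "AATGT", downstream "CC"
split_on_anchor <- function(segment) {
  if (segment$class == "D") stop("D segments have no anchor defined")
  validate_segment(segment)
  off <- segment$anchor_offset
  if (segment$class == "V") {
    cut <- off + 3L
  } else {
    cut <- off
  }
  list(
    upstream = substr(segment$seq, 1L, cut),
    downstream = substr(segment$seq, cut + 1L, nchar(segment$seq))
  )
}

#' Generate a small synthetic germline reference
#'
#' Builds `n_v` V segments (random upstream sequence, a TGT/TGC cysteine
#' anchor, then a short 3' tail that junctional trimming can remove) and
#' `n_j` J segments (a short 5' region, a TTT/TTC phenylalanine anchor
#' followed by a G-x-G motif, then a 3' tail). Deterministic for a fixed
#' seed; all segments pass the anchor invariants and are pairwise distinct.
#'
#' @param n_v,n_j Number of V and J segments (each >= 1).
#' @param seed Integer RNG seed.
#' @param dir Optional directory; when given, `ref.fasta` and `anchors.tsv`
#'   are written there (paths returned in the `files` attribute).
#' @return A `ReferenceSet`.
#' @export
make_toy_reference <- function(n_v, n_j, seed, dir = NULL) {
  if (n_v < 1L || n_j < 1L) stop("n_v and n_j must both be >= 1")
  ref <- withr::with_seed(seed, {
    seen <- character(0)
    vs <- lapply(seq_len(n_v), function(i) {
      repeat {
        seq <- paste0(rand_dna(42L), sample(c("TGT", "TGC"), 1L), rand_dna(3L))
        if (!seq %in% seen) break
      }
      seen <<- c(seen, seq)
      germline_segment(sprintf("TRBV%d", i), "V", seq, 42L)
    })
    js <- lapply(seq_len(n_j), function(i) {
      repeat {
        motif <- paste0(
          sample(c("TTT", "TTC"), 1L),          # F anchor
          "GG", sample(DNA_BASES, 1L),          # G
          rand_dna(3L),                         # x
          "GG", sample(DNA_BASES, 1L)           # G
        )
        seq <- paste0(rand_dna(12L), motif, rand_dna(9L))
        if (!seq %in% seen) break
      }
      seen <<- c(seen, seq)
      germline_segment(sprintf("TRBJ%d", i), "J", seq, 12L)
    })
    reference_set(c(vs, js))
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- write_reference(
      ref,
      file.path(dir, "ref.fasta"), file.path(dir, "anchors.tsv")
    )
    attr(ref, "files") <- files
  }
  ref
}
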