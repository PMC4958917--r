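# Synthetic-data generator: VDJ rearrangements, clone mixtures with tunable
# clonality, and tumor-exome read sets with a known T-cell fraction.
#
# A rearrangement joins a trimmed V 3' end to a trimmed J 5' end with random
# non-templated insertion; the CDR3 spans the conserved V cysteine codon
# through the conserved J phenylalanine/tryptophan codon, both inclusive.
# The read simulator emulates a captured tumor exome: a decoy background,
# unrearranged germline V/J sequence (to exercise detector specificity), and
# T-cell-derived reads whose start positions are uniform over the rearranged
# template footprint, so only a geometry-dependent fraction spans the CDR3.

#' Specify a VDJ rearrangement
#'
#' @param v_id,j_id Segment ids present in the reference.
#' @param v_trim Bases removed from the V 3' end (never the anchor codon).
#' @param j_trim Bases removed from the J 5' end (never the anchor codon).
#' @param n_insert Non-templated nucleotide string inserted at the junction
#'   (possibly empty).
#' @return An object of class `RearrangementSpec`.
#' @export
rearrangement_spec <- function(v_id, j_id, v_trim = 0L, j_trim = 0L, n_insert = "") {
  stopifnot(v_trim >= 0L, j_trim >= 0L)
  n_insert <- toupper(n_insert)
  if (nzchar(n_insert) && grepl("[^ACGT]", n_insert)) {
    stop("n_insert contains non-ACGT characters")
  }
  structure(
    list(
      v_id = v_id, j_id = j_id, v_trim = as.integer(v_trim),
      j_trim = as.integer(j_trim), n_insert = n_insert
    ),
    class = "RearrangementSpec"
  )
}

#' Assemble a rearrangement from a spec and a reference
#'
#' `full_nt` is the trimmed V, the junctional insert, and the trimmed J,
#' concatenated. The CDR3 runs from the V anchor codon through the J anchor
#' codon; the rearrangement is productive when the CDR3 length is divisible
#' by three, its translation is stop-free, and it is bounded by C and F/W.
#'
#' @param spec A `RearrangementSpec`.
#' @param ref A `ReferenceSet`.
#' @return An object of class `Rearrangement` with fields `full_nt`,
#'   `cdr3_nt`, `cdr3_aa`, `productive` plus internal junction coordinates.
#' @export
#' @examples
#' ref <- reference_set(list(
#'   germline_segment("V1", "V", "AAATGT", 3),
#'   germline_segment("J1", "J", "TTTGGCGGCGGA", 0)
#' ))
#' r <- rearrange(rearrangement_spec("V1", "J1", n_insert = "GCCAGCAGC"), ref)
#' r$cdr3_aa # "CASSF"
rearrange <- function(spec, ref) {
  v <- get_segment(ref, spec$v_id)
  j <- get_segment(ref, spec$j_id)
  if (v$class != "V" || j$class != "J") {
    stop("spec must reference a V and a J segment")
  }
  if (spec$v_trim > nchar(v$seq) - (v$anchor_offset + 3L)) {
    stop("v_trim consumes the V anchor codon")
  }
  if (spec$j_trim > j$anchor_offset) {
    stop("j_trim consumes the J anchor codon")
  }
  v_kept <- nchar(v$seq) - spec$v_trim
  j_part <- substr(j$seq, spec$j_trim + 1L, nchar(j$seq))
  full <- paste0(substr(v$seq, 1L, v_kept), spec$n_insert, j_part)
  cdr3_start <- v$anchor_offset + 1L
  j_start <- v_kept + nchar(spec$n_insert) + 1L
  cdr3_end <- j_start + (j$anchor_offset - spec$j_trim) + 2L
  cdr3 <- substr(full, cdr3_start, cdr3_end)
  in_frame <- nchar(cdr3) %% 3L == 0L
  aa <- if (in_frame) translate_nt(cdr3) else ""
  productive <- in_frame && !grepl("*", aa, fixed = TRUE) &&
    startsWith(aa, "C") && substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")
  structure(
    list(
      spec = spec, full_nt = full, cdr3_nt = cdr3, cdr3_aa = aa,
      productive = productive, v_id = v$id, j_id = j$id,
      cdr3_start = cdr3_start, cdr3_end = cdr3_end,
      v_kept = v_kept, j_start = j_start
    ),
    class = "Rearrangement"
  )
}

#' Sample a clone mixture with power-law abundances
#'
#' Clone frequencies are proportional to rank^(-alpha), the single-parameter
#' model that reproduces the oligoclonal profiles seen in deep repertoire
#' sequencing (alpha = 0 gives a uniform repertoire). All sampled clones are
#' productive and have distinct CDR3 nucleotide sequences.
#'
#' @param n_clones Number of clones (>= 1).
#' @param alpha Power-law exponent (>= 0).
#' @param ref A `ReferenceSet`.
#' @param seed Integer RNG seed; results are deterministic for a fixed seed.
#' @return An object of class `CloneMixture`: a list with `clones` (list of
#'   `Rearrangement`), `freq` (numeric, sums to 1) and `clone_id`.
#' @export
sample_mixture <- function(n_clones, alpha, ref, seed) {
  if (n_clones < 1L) stop("n_clones must be >= 1")
  if (alpha < 0) stop("alpha must be >= 0")
  vs <- ref$segments[ref$segments$class == "V", ]
  js <- ref$segments[ref$segments$class == "J", ]
  clones <- withr::with_seed(seed, {
    out <- vector("list", n_clones)
    seen <- character(0)
    for (i in seq_len(n_clones)) {
      for (try in 1:200) {
        vi <- vs[sample.int(nrow(vs), 1L), ]
        ji <- js[sample.int(nrow(js), 1L), ]
        v_down <- nchar(vi$seq) - (vi$anchor_offset + 3L)
        v_trim <- sample.int(v_down + 1L, 1L) - 1L
        j_trim <- sample.int(min(6L, ji$anchor_offset) + 1L, 1L) - 1L
        # choose an insert length that keeps the junction in frame
        base_len <- 3L + (v_down - v_trim) + (ji$anchor_offset - j_trim) + 3L
        ins_len <- (3L - base_len %% 3L) %% 3L + 3L * (sample.int(5L, 1L) - 1L)
        spec <- rearrangement_spec(vi$id, ji$id, v_trim, j_trim, rand_dna(ins_len))
        r <- rearrange(spec, ref)
        if (r$productive && !r$cdr3_nt %in% seen) break
        r <- NULL
      }
      if (is.null(r)) stop("could not sample a productive clone; reference too small?")
      seen <- c(seen, r$cdr3_nt)
      out[[i]] <- r
    }
    out
  })
  freq <- seq_len(n_clones)^(-alpha)
  structure(
    list(
      clones = clones, freq = freq / sum(freq),
      clone_id = sprintf("clone%d", seq_len(n_clones))
    ),
    class = "CloneMixture"
  )
}

#' Simulation configuration for a tumor exome read set
#'
#' @param t_cell_fraction Fraction of cells that are T cells (0..1).
#' @param coverage Mean fold-coverage of the exome.
#' @param read_length Read length in bases (>= 50).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer RNG seed.
#' @param exome_len Captured exome length in bases (default 50 Mb).
#' @param off_target Fraction of reads mapping outside the exome; inflates
#'   the total sequencing yield (default 0.2).
#' @param capture_prob Probability that a CDR3-spanning T-cell fragment is
#'   captured and sequenced; scalar or one value per clone (default 1).
#'   Rearranged fragments hybridize less efficiently to germline capture
#'   probes; this dial models that loss.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(t_cell_fraction, coverage, read_length = 100L,
                       error_rate = 0.001, seed = 1L, exome_len = 5e7,
                       off_target = 0.2, capture_prob = 1) {
  stopifnot(
    t_cell_fraction >= 0, t_cell_fraction <= 1, coverage > 0,
    read_length >= 50L, error_rate >= 0, error_rate < 1,
    exome_len > 0, off_target >= 0, off_target < 1,
    all(capture_prob >= 0), all(capture_prob <= 1)
  )
  structure(
    list(
      t_cell_fraction = t_cell_fraction, coverage = coverage,
      read_length = as.integer(read_length), error_rate = error_rate,
      seed = seed, exome_len = exome_len, off_target = off_target,
      capture_prob = capture_prob
    ),
    class = "SimConfig"
  )
}

#' Count template start positions that span the CDR3 with caller flanks
#'
#' Brute-force enumeration over every read start position on a clone's
#' rearranged template of the positions whose read fully covers the CDR3 and
#' retains at least `min_v`/`min_j` aligned germline bases on either side.
#' @noRd
detectable_positions <- function(rearr, read_length, min_v = 20L, min_j = 12L) {
  lf <- nchar(rearr$full_nt)
  starts <- (2L - read_length):lf  # all reads overlapping the template
  read_end <- starts + read_length - 1L
  cov_start <- pmax(starts, 1L)
  cov_end <- pmin(read_end, lf)
  v_aligned <- pmax(0L, pmin(cov_end, rearr$v_kept) - cov_start + 1L)
  j_aligned <- pmax(0L, cov_end - pmax(cov_start, rearr$j_start) + 1L)
  spans <- starts <= rearr$cdr3_start & read_end >= rearr$cdr3_end
  sum(spans & v_aligned >= min_v & j_aligned >= min_j)
}

#' Simulate a tumor-exome read set with a ground-truth manifest
#'
#' Emits `round(exome_len * coverage / read_length / (1 - off_target))`
#' single-end reads: T-cell reads drawn from the clone mixture (total count
#' binomial in the T-cell fraction, clone assignment multinomial in the
#' clone frequencies, start position uniform over the clone template
#' footprint of `|full_nt| + read_length - 1` positions), background reads
#' from the unrearranged germline V/J contig, and the remainder from a
#' random decoy contig. Per-base substitution errors are applied at
#' `error_rate`. No background read contains any clone's CDR3 (re-drawn on
#' collision). Identical seeds give byte-identical FASTQ output.
#'
#' In the BAM emission, CDR3-spanning T-cell reads are written either
#' unmapped or soft-clipped at the locus window start; germline-contig reads
#' are placed inside the locus window (alternating strands); decoy reads map
#' to the decoy contig.
#'
#' @param mixture A `CloneMixture`.
#' @param config A `SimConfig`.
#' @param ref The `ReferenceSet` the mixture was built from.
#' @param fastq,bam,manifest Optional output paths (FASTQ, indexed BAM,
#'   TSV manifest with columns `read_id origin spans_cdr3 clone_id`).
#' @return Invisibly, a list of class `SimReadSet` with elements `reads`
#'   (data.frame: read_id, seq, source, clone_id, spans_cdr3), `manifest`,
#'   `n_total`, and any output paths.
#' @export
simulate_reads <- function(mixture, config, ref, fastq = NULL, bam = NULL,
                           manifest = NULL) {
  if (length(mixture$clones) == 0L) stop("empty clone mixture")
  rl <- config$read_length
  n_clones <- length(mixture$clones)
  cdr3_lens <- vapply(mixture$clones, function(r) nchar(r$cdr3_nt), 0L)
  if (any(cdr3_lens > rl)) {
    warning("read_length < CDR3 length for ", sum(cdr3_lens > rl),
            " clone(s); those CDR3s cannot be fully spanned")
  }
  capture <- rep_len(config$capture_prob, n_clones)
  n_total <- round(config$exome_len * config$coverage / rl / (1 - config$off_target))

  res <- withr::with_seed(config$seed, {
    # clone templates padded so reads can start anywhere on the footprint
    ext <- vapply(mixture$clones, function(r) {
      paste0(rand_dna(rl - 1L), r$full_nt, rand_dna(rl - 1L))
    }, "")
    footprint <- vapply(mixture$clones, function(r) nchar(r$full_nt), 0L) + rl - 1L
    mean_fp <- sum(mixture$freq * footprint)

    f <- config$t_cell_fraction
    n_t <- if (f > 0) stats::rbinom(1L, n_total, min(1, f * mean_fp / config$exome_len)) else 0L
    clone_of <- if (n_t > 0) {
      sample.int(n_clones, n_t, replace = TRUE, prob = mixture$freq)
    } else integer(0)

    t_seq <- character(n_t)
    t_spans <- logical(n_t)
    t_keep <- logical(n_t)
    if (n_t > 0) {
      u <- integer(n_t)
      for (c in seq_len(n_clones)) {
        idx <- which(clone_of == c)
        if (!length(idx)) next
        u[idx] <- sample.int(footprint[c], length(idx), replace = TRUE) - 1L
        t_seq[idx] <- substring(ext[c], u[idx] + 1L, u[idx] + rl)
        r <- mixture$clones[[c]]
        # template coordinate of the read start relative to full_nt
        s_full <- u[idx] - (rl - 1L) + 1L
        t_spans[idx] <- s_full <= r$cdr3_start & (s_full + rl - 1L) >= r$cdr3_end
        t_keep[idx] <- !t_spans[idx] |
          stats::runif(length(idx)) < capture[c]
      }
    }

    # background contigs: germline V/J with long spacers, plus a decoy
    spacer_len <- max(150L, rl + 50L)
    segs <- ref$segments$seq
    pieces <- character(2L * length(segs) + 1L)
    pieces[seq(1L, length(pieces), 2L)] <- vapply(
      seq_len(length(segs) + 1L), function(i) rand_dna(spacer_len), ""
    )
    pieces[seq(2L, length(pieces) - 1L, 2L)] <- segs
    germ <- paste(pieces, collapse = "")
    g_len <- nchar(germ)
    decoy <- rand_dna(10000L)

    n_bg <- n_total - n_t
    n_g <- stats::rbinom(1L, n_bg, min(1, g_len / config$exome_len))
    n_d <- n_bg - n_g

    draw_bg <- function(contig, n) {
      if (n == 0L) return(list(seq = character(0), pos = integer(0)))
      pos <- sample.int(nchar(contig) - rl + 1L, n, replace = TRUE)
      sq <- substring(contig, pos, pos + rl - 1L)
      # re-draw any read containing a clone CDR3 (either strand)
      for (iter in 1:20) {
        bad <- rep(FALSE, n)
        for (cd in vapply(mixture$clones, `[[`, "", "cdr3_nt")) {
          bad <- bad | grepl(cd, sq, fixed = TRUE) | grepl(revcomp(cd), sq, fixed = TRUE)
        }
        if (!any(bad)) break
        pos[bad] <- sample.int(nchar(contig) - rl + 1L, sum(bad), replace = TRUE)
        sq[bad] <- substring(contig, pos[bad], pos[bad] + rl - 1L)
      }
      list(seq = sq, pos = pos)
    }
    g <- draw_bg(germ, n_g)
    d <- draw_bg(decoy, n_d)

    keep_idx <- which(t_keep)
    reads <- data.frame(
      read_id = c(
        sprintf("t%07d", seq_along(keep_idx)),
        sprintf("g%07d", seq_len(n_g)),
        sprintf("d%07d", seq_len(n_d))
      ),
      seq = c(t_seq[keep_idx], g$seq, d$seq),
      source = c(
        rep("tcell", length(keep_idx)), rep("germline", n_g), rep("decoy", n_d)
      ),
      clone_id = c(
        mixture$clone_id[clone_of[keep_idx]], rep("", n_g), rep("", n_d)
      ),
      spans_cdr3 = c(t_spans[keep_idx], rep(FALSE, n_g + n_d)),
      stringsAsFactors = FALSE
    )

    if (config$error_rate > 0 && nrow(reads) > 0) {
      n_mut <- stats::rbinom(nrow(reads), rl, config$error_rate)
      for (i in which(n_mut > 0L)) {
        pos <- sample.int(rl, n_mut[i])
        s <- reads$seq[i]
        for (p in pos) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
        }
        reads$seq[i] <- s
      }
    }

    list(reads = reads, g_pos = g$pos, d_pos = d$pos,
         decoy_len = nchar(decoy), g_len = g_len)
  })

  reads <- res$reads
  man <- data.frame(
    read_id = reads$read_id,
    origin = ifelse(reads$source == "tcell", reads$clone_id, "background"),
    spans_cdr3 = reads$spans_cdr3,
    clone_id = reads$clone_id,
    stringsAsFactors = FALSE
  )

  out <- structure(
    list(reads = reads, manifest = man, n_total = n_total,
         config = config, fastq = fastq, bam = bam),
    class = "SimReadSet"
  )

  if (!is.null(fastq)) {
    qual <- strrep("I", rl)
    writeLines(
      as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual)),
      fastq
    )
  }
  if (!is.null(manifest)) {
    utils::write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bam)) {
    out$bam <- write_sim_bam(out, res, ref, bam)
  }
  invisible(out)
}

#' Render a simulated read set as a coordinate-sorted, indexed BAM
#' @noRd
write_sim_bam <- function(sim, res, ref, bam_path) {
  reads <- sim$reads
  rl <- sim$config$read_length
  win <- ref$locus_window
  qual <- strrep("I", rl)

  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:decoy\tLN:%d", res$decoy_len),
    sprintf("@SQ\tSN:%s\tLN:%d", win$chrom, as.integer(win$end + 1000))
  )

  n <- nrow(reads)
  flag <- integer(n); rname <- character(n); pos <- integer(n)
  mapq <- integer(n); cigar <- character(n); seqout <- reads$seq

  is_t <- reads$source == "tcell"
  is_g <- reads$source == "germline"
  is_d <- reads$source == "decoy"

  # decoy reads: plain mapped records on the decoy contig
  rname[is_d] <- "decoy"; pos[is_d] <- res$d_pos
  cigar[is_d] <- paste0(rl, "M"); mapq[is_d] <- 60L

  # germline reads: inside the locus window, alternating strands
  gi <- which(is_g)
  rname[gi] <- win$chrom
  pos[gi] <- as.integer(win$start) + res$g_pos - 1L
  cigar[gi] <- paste0(rl, "M"); mapq[gi] <- 60L
  rev <- gi[seq_along(gi) %% 2L == 0L]
  flag[rev] <- 16L
  seqout[rev] <- revcomp(reads$seq[rev])

  # T-cell reads: CDR3-spanning ones are unmapped or soft-clipped at the
  # window start; non-spanning ones map inside the window
  ti <- which(is_t)
  span <- reads$spans_cdr3[ti]
  unmapped <- ti[span][seq_len(sum(span)) %% 2L == 1L]
  clipped <- setdiff(ti[span], unmapped)
  plain <- ti[!span]
  flag[unmapped] <- 4L; rname[unmapped] <- "*"; pos[unmapped] <- 0L
  cigar[unmapped] <- "*"; mapq[unmapped] <- 0L
  rname[clipped] <- win$chrom; pos[clipped] <- as.integer(win$start)
  cigar[clipped] <- paste0("1M", rl - 1L, "S"); mapq[clipped] <- 30L
  rname[plain] <- win$chrom; pos[plain] <- as.integer(win$start)
  cigar[plain] <- paste0(rl, "M"); mapq[plain] <- 30L

  lines <- paste(
    reads$read_id, flag, rname, pos, mapq, cigar,
    "*", 0L, 0L, seqout, qual,
    sep = "\t"
  )
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, lines), sam)
  out <- sam_to_bam(sam, bam_path)
  unlink(sam)
  out
}

#' Convert a SAM text file into a coordinate-sorted, indexed BAM
#'
#' @param sam Path to a SAM file.
#' @param bam_path Desired output BAM path.
#' @return The BAM path, with a `.bai` index alongside.
#' @export
sam_to_bam <- function(sam, bam_path) {
  tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  dest <- sub("\\.bam$", "", bam_path)
  sorted <- Rsamtools::sortBam(tmp, dest)
  Rsamtools::indexBam(sorted)
  unlink(tmp)
  sorted
}
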