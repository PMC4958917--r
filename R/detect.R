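# The core caller: seed-and-extend ungapped alignment of candidate reads
# against germline V and J segments, anchor projection to extract the CDR3
# junction, productivity filtering with optional out-of-frame rescue, and
# clonotype aggregation with Hamming-1 error collapse.
#
# Alignment is deliberately ungapped (substitutions only): the V/J flanks of
# a CDR3 junction in a 100 bp read rarely need gaps, and the restriction
# keeps the exact brute-force oracle used in the tests cheap.

#' Detection parameters
#'
#' @param seed_k k-mer length used to seed alignments (default 12; must not
#'   exceed `min_j_match`).
#' @param min_v_match,min_j_match Minimum aligned bases against the V / J
#'   segment for a hit (defaults 20 and 12).
#' @param max_mismatch_rate Maximum mismatch fraction within the aligned
#'   interval (default 0.1).
#' @param rescue_out_of_frame Return non-productive junctions as rescued
#'   calls instead of dropping them (default FALSE).
#' @param error_collapse Merge singleton clonotypes within Hamming distance
#'   1 of a clonotype supported by two or more reads (default TRUE).
#' @return An object of class `DetectParams`.
#' @export
detect_params <- function(seed_k = 12L, min_v_match = 20L, min_j_match = 12L,
                          max_mismatch_rate = 0.1, rescue_out_of_frame = FALSE,
                          error_collapse = TRUE) {
  if (seed_k > min_j_match) stop("seed_k must not exceed min_j_match")
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 0.5) {
    stop("max_mismatch_rate must be in [0, 0.5)")
  }
  structure(
    list(
      seed_k = as.integer(seed_k), min_v_match = as.integer(min_v_match),
      min_j_match = as.integer(min_j_match),
      max_mismatch_rate = max_mismatch_rate,
      rescue_out_of_frame = isTRUE(rescue_out_of_frame),
      error_collapse = isTRUE(error_collapse)
    ),
    class = "DetectParams"
  )
}

#' Build a k-mer index over the V and J segments of a reference
#'
#' @param ref A `ReferenceSet`.
#' @param k Seed k-mer length.
#' @return A list with one index per class (`V`, `J`): an environment
#'   mapping k-mer to a matrix of (segment row, 1-based segment position),
#'   plus the segment table.
#' @export
segment_index <- function(ref, k = 12L) {
  build <- function(segs) {
    env <- new.env(hash = TRUE, parent = emptyenv())
    kmer_set <- character(0)
    for (i in seq_len(nrow(segs))) {
      km <- seq_kmers(segs$seq[i], k)
      for (p in seq_along(km)) {
        cur <- get0(km[p], envir = env)
        env[[km[p]]] <- rbind(cur, c(i, p))
      }
      kmer_set <- c(kmer_set, km)
    }
    list(env = env, kmers = unique(kmer_set), segments = segs)
  }
  out <- list(
    V = build(ref$segments[ref$segments$class == "V", , drop = FALSE]),
    J = build(ref$segments[ref$segments$class == "J", , drop = FALSE]),
    k = as.integer(k)
  )
  class(out) <- "SegmentIndex"
  out
}

#' Align a read against one class of germline segments
#'
#' Seed-and-extend, substitutions only: shared k-mers define diagonals;
#' each run of seed matches is extended outward under +1/-1 scoring,
#' keeping the best-prefix extension on either side (the optimal ungapped
#' interval containing the seed run). A hit is returned only when
#' the aligned length reaches the class minimum and the mismatch fraction
#' stays within `max_mismatch_rate`. Ties are broken by higher score, then
#' lexicographic segment id.
#'
#' @param read_seq A nucleotide string.
#' @param ref A `ReferenceSet` (or prebuilt [segment_index()] via `index`).
#' @param class `"V"` or `"J"`.
#' @param params A `DetectParams`.
#' @param index Optional prebuilt `SegmentIndex` to avoid re-indexing.
#' @return A list (segment id, read/segment intervals, score = aligned bases
#'   net of mismatches, mismatches, aligned length) or `NULL` when nothing
#'   reaches the thresholds.
#' @export
align_segment <- function(read_seq, ref = NULL, class = c("V", "J"),
                          params = detect_params(), index = NULL) {
  class <- match.arg(class)
  if (is.null(index)) {
    if (is.null(ref)) stop("either ref or index must be supplied")
    index <- segment_index(ref, params$seed_k)
  }
  idx <- index[[class]]
  if (nrow(idx$segments) == 0L) stop("no ", class, " segments in reference")
  min_len <- if (class == "V") params$min_v_match else params$min_j_match

  k <- index$k
  read_seq <- toupper(read_seq)
  km <- seq_kmers(read_seq, k)
  if (!length(km)) return(NULL)
  hits <- mget(km, envir = idx$env, ifnotfound = list(NULL))

  # collect (segment, diagonal, read position) triples; diagonal d maps
  # read position i to segment position i + d
  seg_i <- integer(0); diag <- integer(0); rpos <- integer(0)
  for (rp in seq_along(hits)) {
    h <- hits[[rp]]
    if (is.null(h)) next
    seg_i <- c(seg_i, h[, 1L])
    diag <- c(diag, h[, 2L] - rp)
    rpos <- c(rpos, rep(rp, nrow(h)))
  }
  if (!length(seg_i)) return(NULL)

  rl <- nchar(read_seq)
  read_chars <- charToRaw(read_seq)
  best <- NULL
  pairs <- unique(cbind(seg_i, diag))
  for (p in seq_len(nrow(pairs))) {
    si <- unname(pairs[p, 1L]); d <- unname(pairs[p, 2L])
    seg <- idx$segments$seq[si]
    sl <- nchar(seg)
    lo <- max(1L, 1L - d)
    hi <- min(rl, sl - d)
    if (hi - lo + 1L < min_len) next
    is_match <- read_chars[lo:hi] == charToRaw(seg)[(lo + d):(hi + d)]

    # group this diagonal's seed positions into runs of consecutive
    # matches and extend each run outward
    sp <- sort(unique(rpos[seg_i == si & diag == d])) - lo + 1L
    runs <- split(sp, cumsum(c(1L, diff(sp) != 1L)))
    for (run in runs) {
      s0 <- run[1L]
      e0 <- run[length(run)] + k - 1L
      iv <- extend_seed_block(is_match, s0, e0, min_len,
                              params$max_mismatch_rate)
      if (is.null(iv)) next
      len <- iv$len
      mism <- iv$mism
      cand <- list(
        id = idx$segments$id[si],
        read_start = lo + iv$start - 1L,
        read_end = lo + iv$end - 1L,
        seg_start = lo + iv$start - 1L + d,
        seg_end = lo + iv$end - 1L + d,
        score = iv$matches - mism,
        mismatches = mism,
        aligned_len = len,
        diag = d,
        anchor_offset = idx$segments$anchor_offset[si]
      )
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$id < best$id) ||
          (cand$score == best$score && cand$id == best$id &&
             cand$read_start < best$read_start)) {
        best <- cand
      }
    }
  }
  best
}

#' Call a CDR3 junction in a single read
#'
#' Requires a V hit and a J hit on the same strand with the V read-interval
#' ending before the J read-interval ends, and both anchor codons projected
#' inside the read through their alignment diagonals. The CDR3 is the read
#' substring from the projected V anchor start through the projected J
#' anchor end. Both strands are attempted; the higher combined score wins.
#' Productive junctions (length divisible by 3, stop-free, C...F/W bounded)
#' are always returned; non-productive ones only under
#' `rescue_out_of_frame` (flagged `rescued`, with empty `cdr3_aa`).
#'
#' @param read_seq Nucleotide string of the candidate read.
#' @param ref A `ReferenceSet`.
#' @param params A `DetectParams`.
#' @param read_id Identifier carried into the call.
#' @param index Optional prebuilt [segment_index()].
#' @return An object of class `Cdr3Call` (a one-row data.frame with columns
#'   read_id, v_id, j_id, cdr3_nt, cdr3_aa, productive, rescued, v_score,
#'   j_score) or `NULL` when the read holds no junction.
#' @export
call_cdr3 <- function(read_seq, ref, params = detect_params(),
                      read_id = NA_character_, index = NULL) {
  read_seq <- toupper(read_seq)
  if (nchar(read_seq) < params$min_v_match + params$min_j_match) return(NULL)
  if (is.null(index)) index <- segment_index(ref, params$seed_k)

  try_strand <- function(s) {
    v <- align_segment(s, class = "V", params = params, index = index)
    if (is.null(v)) return(NULL)
    j <- align_segment(s, class = "J", params = params, index = index)
    if (is.null(j)) return(NULL)
    if (v$read_end >= j$read_end) return(NULL)
    a_v <- v$anchor_offset + 1L - v$diag   # 1-based read position of V anchor
    a_j <- j$anchor_offset + 1L - j$diag
    if (a_v < 1L || a_j + 2L > nchar(s) || a_j < a_v + 3L) return(NULL)
    list(v = v, j = j, a_v = a_v, a_j = a_j, seq = s,
         score = v$score + j$score)
  }

  fwd <- try_strand(read_seq)
  rev <- try_strand(revcomp(read_seq))
  hit <- if (is.null(fwd)) rev else if (is.null(rev)) fwd else {
    if (rev$score > fwd$score) rev else fwd
  }
  if (is.null(hit)) return(NULL)

  cdr3 <- substr(hit$seq, hit$a_v, hit$a_j + 2L)
  in_frame <- nchar(cdr3) %% 3L == 0L
  aa <- if (in_frame) translate_nt(cdr3) else ""
  productive <- in_frame && !grepl("*", aa, fixed = TRUE) &&
    startsWith(aa, "C") && substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")
  if (!productive && !params$rescue_out_of_frame) return(NULL)

  out <- data.frame(
    read_id = read_id,
    v_id = hit$v$id, j_id = hit$j$id,
    cdr3_nt = cdr3,
    cdr3_aa = if (productive) aa else "",
    productive = productive,
    rescued = !productive,
    v_score = hit$v$score, j_score = hit$j$score,
    stringsAsFactors = FALSE
  )
  class(out) <- c("Cdr3Call", class(out))
  out
}

#' Aggregate CDR3 calls into clonotypes
#'
#' Groups calls by (cdr3_nt, v_id, j_id). With `error_collapse`, any
#' clonotype supported by exactly one read whose CDR3 is within Hamming
#' distance 1 (equal length, same V/J) of a clonotype with two or more
#' reads is merged into it; the largest neighbor wins, ties broken by
#' lexicographically smallest CDR3. Read ids are preserved through merges.
#'
#' @param calls A list of `Cdr3Call` objects (or a data.frame of them).
#' @param params A `DetectParams` (controls `error_collapse`).
#' @return A data.frame of clonotypes (cdr3_nt, cdr3_aa, v_id, j_id,
#'   read_count, productive, read_ids list-column), ordered by descending
#'   read count then CDR3.
#' @export
aggregate_clonotypes <- function(calls, params = detect_params()) {
  empty <- data.frame(
    cdr3_nt = character(0), cdr3_aa = character(0), v_id = character(0),
    j_id = character(0), read_count = integer(0), productive = logical(0),
    stringsAsFactors = FALSE
  )
  empty$read_ids <- list()
  if (is.data.frame(calls)) {
    df <- calls
  } else {
    calls <- Filter(Negate(is.null), calls)
    if (!length(calls)) return(empty)
    df <- do.call(rbind, calls)
  }
  if (nrow(df) == 0L) return(empty)

  key <- paste(df$cdr3_nt, df$v_id, df$j_id, sep = "\r")
  grp <- split(seq_len(nrow(df)), key)
  clono <- do.call(rbind, lapply(grp, function(ix) {
    data.frame(
      cdr3_nt = df$cdr3_nt[ix[1]], cdr3_aa = df$cdr3_aa[ix[1]],
      v_id = df$v_id[ix[1]], j_id = df$j_id[ix[1]],
      read_count = length(ix), productive = df$productive[ix[1]],
      stringsAsFactors = FALSE
    )
  }))
  clono$read_ids <- lapply(grp, function(ix) df$read_id[ix])
  rownames(clono) <- NULL

  if (params$error_collapse) {
    majors <- which(clono$read_count >= 2L)
    singles <- which(clono$read_count == 1L)
    drop <- integer(0)
    for (s in singles) {
      if (!length(majors)) break
      cand <- majors[
        clono$v_id[majors] == clono$v_id[s] &
          clono$j_id[majors] == clono$j_id[s] &
          nchar(clono$cdr3_nt[majors]) == nchar(clono$cdr3_nt[s])
      ]
      cand <- cand[vapply(cand, function(m) hamming(clono$cdr3_nt[m], clono$cdr3_nt[s]) <= 1L, TRUE)]
      if (!length(cand)) next
      # largest neighbor wins; ties by lexicographic cdr3_nt
      ord <- order(-clono$read_count[cand], clono$cdr3_nt[cand])
      m <- cand[ord[1L]]
      clono$read_count[m] <- clono$read_count[m] + 1L
      clono$read_ids[[m]] <- c(clono$read_ids[[m]], clono$read_ids[[s]])
      drop <- c(drop, s)
    }
    if (length(drop)) clono <- clono[-drop, , drop = FALSE]
  }
  clono <- clono[order(-clono$read_count, clono$cdr3_nt), , drop = FALSE]
  rownames(clono) <- NULL
  clono
}

#' Fast strand-aware prescreen: reads sharing a V and a J seed k-mer
#' @noRd
prescreen_reads <- function(seqs, index) {
  k <- index$k
  vk <- index$V$kmers
  jk <- index$J$kmers
  screen_one <- function(s) {
    km <- seq_kmers(s, k)
    length(km) && any(km %in% vk) && any(km %in% jk)
  }
  fwd <- vapply(seqs, screen_one, TRUE, USE.NAMES = FALSE)
  out <- fwd
  if (any(!fwd)) {
    rc <- revcomp(seqs[!fwd])
    out[!fwd] <- vapply(rc, screen_one, TRUE, USE.NAMES = FALSE)
  }
  out
}

#' Detect the CDR3 repertoire of one sample
#'
#' Maps [call_cdr3()] over the candidate reads, aggregates clonotypes, and
#' normalizes: `cdr3_rpm = cdr3_read_count / total_reads * 1e6`.
#'
#' @param candidates A `CandidateReadSet` (from [harvest()],
#'   [candidate_set_from_fastq()], or a simulated read set).
#' @param ref A `ReferenceSet`.
#' @param params A `DetectParams`.
#' @return An object of class `SampleRepertoire`: list with `sample_id`,
#'   `clonotypes` (data.frame), `cdr3_read_count`, `total_reads`,
#'   `cdr3_rpm`.
#' @export
detect_sample <- function(candidates, ref, params = detect_params()) {
  if (is.null(candidates$total_reads) || candidates$total_reads <= 0) {
    stop("candidates$total_reads must be positive")
  }
  index <- segment_index(ref, params$seed_k)
  reads <- candidates$reads
  calls <- list()
  if (nrow(reads) > 0L) {
    keep <- prescreen_reads(reads$seq, index)
    calls <- lapply(which(keep), function(i) {
      call_cdr3(reads$seq[i], ref, params, read_id = reads$read_id[i],
                index = index)
    })
  }
  clono <- aggregate_clonotypes(calls, params)
  n_cdr3 <- sum(clono$read_count)
  structure(
    list(
      sample_id = candidates$sample_id,
      clonotypes = clono,
      cdr3_read_count = n_cdr3,
      total_reads = candidates$total_reads,
      cdr3_rpm = n_cdr3 / candidates$total_reads * 1e6
    ),
    class = "SampleRepertoire"
  )
}

#' @export
print.SampleRepertoire <- function(x, ...) {
  cat(sprintf(
    "SampleRepertoire '%s': %d clonotypes, %d CDR3 reads / %s total = %.4g RPM\n",
    x$sample_id, nrow(x$clonotypes), x$cdr3_read_count,
    format(x$total_reads, big.mark = ","), x$cdr3_rpm
  ))
  invisible(x)
}

#' Write a sample repertoire as TSV
#'
#' Columns: `sample_id cdr3_nt cdr3_aa v_id j_id read_count productive
#' read_ids` (read ids comma-separated).
#'
#' @param repertoire A `SampleRepertoire`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_repertoire <- function(repertoire, path) {
  cl <- repertoire$clonotypes
  out <- data.frame(
    sample_id = rep(repertoire$sample_id, nrow(cl)),
    cl[, c("cdr3_nt", "cdr3_aa", "v_id", "j_id", "read_count", "productive")],
    read_ids = vapply(cl$read_ids, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  attr_line <- sprintf(
    "# total_reads=%d cdr3_read_count=%d cdr3_rpm=%.10g",
    repertoire$total_reads, repertoire$cdr3_read_count, repertoire$cdr3_rpm
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample repertoire written by [write_repertoire()]
#'
#' @param path Path to a repertoire TSV.
#' @return A `SampleRepertoire`.
#' @export
read_repertoire <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- as.numeric(
    regmatches(first, gregexpr("(?<==)[0-9.eE+-]+", first, perl = TRUE))[[1]]
  )
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(cdr3_nt = "character", cdr3_aa = "character"))
  cl <- df[, c("cdr3_nt", "cdr3_aa", "v_id", "j_id", "read_count", "productive")]
  cl$cdr3_aa[is.na(cl$cdr3_aa)] <- ""
  cl$read_ids <- strsplit(df$read_ids, ",", fixed = TRUE)
  structure(
    list(
      sample_id = if (nrow(df)) df$sample_id[1] else sub("\\.tsv$", "", basename(path)),
      clonotypes = cl,
      cdr3_read_count = as.integer(meta[2]),
      total_reads = meta[1],
      cdr3_rpm = meta[3]
    ),
    class = "SampleRepertoire"
  )
}

#' Treat a simulated read set as detector candidates
#'
#' Mirrors what [harvest()] would return on the simulator's BAM: all T-cell
#' reads (written unmapped or locus-soft-clipped) and germline-contig reads
#' (locus-mapped) are candidates; decoy reads are not.
#'
#' @param sim A `SimReadSet` from [simulate_reads()].
#' @param sample_id Sample label.
#' @return A `CandidateReadSet`.
#' @export
sim_candidates <- function(sim, sample_id = "sim") {
  reads <- sim$reads[sim$reads$source != "decoy", , drop = FALSE]
  structure(
    list(
      sample_id = sample_id,
      reads = data.frame(
        read_id = reads$read_id, seq = reads$seq,
        source = ifelse(reads$source == "tcell" & reads$spans_cdr3,
                        "unmapped", "locus_mapped"),
        clipped = NA,
        stringsAsFactors = FALSE
      ),
      total_reads = sim$n_total
    ),
    class = "CandidateReadSet"
  )
}
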