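# Internal helpers shared across modules. Sequences are plain uppercase
# character strings over {A,C,G,T}; intra-sequence offsets are 0-based,
# genomic coordinates 1-based inclusive.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Translate a nucleotide string with the standard genetic code
#' @noRd
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return("")
  stopifnot(n %% 3L == 0L)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Reverse complement for a character vector of sequences
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' All k-mers of a single sequence (1-based start positions as names)
#' @noRd
seq_kmers <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character(0))
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

#' Hamming distance between equal-length strings
#' @noRd
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

#' Pareto-optimal outward extensions of a seed block
#'
#' For a sequence of +/-1 extension steps, the only extension lengths that
#' can take part in a constrained optimum are the zero extension and the
#' first occurrence of each new cumulative-gain maximum (mismatch count is
#' non-decreasing along the extension, so later points with no higher gain
#' are dominated).
#' @noRd
pareto_extensions <- function(steps_match) {
  if (!length(steps_match)) {
    return(list(gain = 0L, mism = 0L, len = 0L))
  }
  g <- cumsum(ifelse(steps_match, 1L, -1L))
  mm <- cumsum(!steps_match)
  best <- 0L
  keep <- integer(0)
  for (j in seq_along(g)) {
    if (g[j] > best) { best <- g[j]; keep <- c(keep, j) }
  }
  list(gain = c(0L, g[keep]), mism = c(0L, mm[keep]), len = c(0L, keep))
}

#' Best seed-containing interval under +1/-1 scoring with constraints
#'
#' Extends a block of seed matches `[seed_start, seed_end]` (all TRUE in
#' `is_match`) outward, choosing among Pareto-optimal left/right extension
#' pairs the highest-scoring interval whose length reaches `min_len` and
#' whose mismatch fraction stays within `max_mm_rate` (exact for rates
#' below 0.5). Returns NULL when no extension satisfies the constraints.
#' @noRd
extend_seed_block <- function(is_match, seed_start, seed_end,
                              min_len, max_mm_rate) {
  n <- length(is_match)
  block <- seed_end - seed_start + 1L
  left <- pareto_extensions(if (seed_start > 1L)
    rev(is_match[1:(seed_start - 1L)]) else logical(0))
  right <- pareto_extensions(if (seed_end < n)
    is_match[(seed_end + 1L):n] else logical(0))

  score <- block + outer(left$gain, right$gain, `+`)
  mism <- outer(left$mism, right$mism, `+`)
  len <- block + outer(left$len, right$len, `+`)
  ok <- len >= min_len & mism <= max_mm_rate * len
  if (!any(ok)) return(NULL)
  score[!ok] <- -Inf
  # highest score; ties by fewest mismatches, then shortest interval
  best <- which(score == max(score) & ok)
  best <- best[order(mism[best], len[best])][1L]
  li <- (best - 1L) %% length(left$gain) + 1L
  ri <- (best - 1L) %/% length(left$gain) + 1L
  list(
    start = seed_start - left$len[li],
    end = seed_end + right$len[ri],
    score = score[best],
    matches = (len[best] + score[best]) %/% 2L,
    mism = mism[best],
    len = len[best]
  )
}

#' Parse "chr7:142000817-142510993" or pass through a window list
#' @noRd
as_window <- function(window) {
  if (is.character(window) && length(window) == 1L) {
    m <- regmatches(window, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", window))[[1]]
    if (length(m) != 4L) {
      stop("cannot parse genomic window '", window, "' (expected chrom:start-end)")
    }
    window <- list(
      chrom = m[2],
      start = as.numeric(gsub(",", "", m[3])),
      end = as.numeric(gsub(",", "", m[4]))
    )
  }
  stopifnot(is.list(window), all(c("chrom", "start", "end") %in% names(window)))
  if (window$start > window$end) stop("window start exceeds end")
  window
}

#' Derive a child RNG seed from a base seed, kept within 32-bit range
#' @noRd
child_seed <- function(seed, i) {
  (as.numeric(seed) * 1103L + i * 12347) %% 2147483629
}
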