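# Cohort-level scoring: CDR3 RPM deciles (the iDNA score), clonal diversity
# ratio, clonality, TCRB expression normalization, DNA/RNA concordance
# classes and clonotype sharing.

#' Assemble a cohort table
#'
#' One row per (sample, source). `cdr3_rpm` and `n_clonotypes` typically
#' come from [detect_sample()] repertoires.
#'
#' @param sample_id,source,cdr3_rpm,n_clonotypes,total_reads Equal-length
#'   vectors; `source` entries are `"DNA"` or `"RNA"`.
#' @return A data.frame of class `CohortTable`.
#' @export
cohort_table <- function(sample_id, source, cdr3_rpm, n_clonotypes,
                         total_reads = NA_real_) {
  source <- as.character(source)
  if (!all(source %in% c("DNA", "RNA"))) stop("source must be DNA or RNA")
  df <- data.frame(
    sample_id = as.character(sample_id), source = source,
    cdr3_rpm = as.numeric(cdr3_rpm), n_clonotypes = as.integer(n_clonotypes),
    total_reads = as.numeric(total_reads), stringsAsFactors = FALSE
  )
  if (anyDuplicated(df[, c("sample_id", "source")])) {
    stop("(sample_id, source) pairs must be unique")
  }
  if (any(df$cdr3_rpm < 0)) stop("cdr3_rpm must be non-negative")
  if (any((df$n_clonotypes == 0L) != (df$cdr3_rpm == 0))) {
    stop("n_clonotypes must be zero exactly when cdr3_rpm is zero")
  }
  class(df) <- c("CohortTable", class(df))
  df
}

#' iDNA decile scores for a cohort
#'
#' Samples without CDR3 reads score 0; samples with CDR3 reads are ranked
#' by CDR3 RPM and cut into ten equal-frequency bins scoring 1-10 (ties
#' share the lower bin), so the score is monotone non-decreasing in RPM and
#' `score == 0` exactly when `cdr3_rpm == 0`.
#'
#' @param cohort A `CohortTable` (or compatible data.frame).
#' @param source Which rows to score: `"DNA"` (default) or `"RNA"`.
#' @return A data.frame with `sample_id`, `cdr3_rpm`, `score` (integer
#'   0-10).
#' @export
idna_scores <- function(cohort, source = "DNA") {
  rows <- cohort[cohort$source == source, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no cohort rows with source ", source)
  score <- integer(nrow(rows))
  pos <- which(rows$cdr3_rpm > 0)
  if (length(pos) > 0L) {
    if (length(pos) < 10L) {
      warning("fewer than 10 samples with CDR3 reads; ",
              "decile bins are proportional quantile bins")
    }
    r <- rank(rows$cdr3_rpm[pos], ties.method = "min")
    score[pos] <- as.integer(ceiling(10 * r / length(pos)))
  }
  data.frame(
    sample_id = rows$sample_id, cdr3_rpm = rows$cdr3_rpm, score = score,
    stringsAsFactors = FALSE
  )
}

#' Clonal diversity ratio
#'
#' The number of clonotypes divided by the normalized CDR3 read count; an
#' approximation to clonal diversity usable at shallow repertoire depth.
#' Defined only for samples with CDR3 reads.
#'
#' @param n_clonotypes Clonotype count(s).
#' @param cdr3_rpm Matching CDR3 RPM value(s), all > 0.
#' @return `n_clonotypes / cdr3_rpm`.
#' @export
diversity_ratio <- function(n_clonotypes, cdr3_rpm) {
  if (any(cdr3_rpm <= 0)) {
    stop("diversity ratio undefined for samples without CDR3 reads (rpm = 0)")
  }
  n_clonotypes / cdr3_rpm
}

#' Clonality of a clone frequency distribution
#'
#' `1 - H / ln(R)` where `H` is the Shannon entropy (natural log) of the
#' clone frequencies and `R` the number of clones: 0 for a perfectly even
#' repertoire, 1 for a monoclonal one (R = 1 scores 1 by convention).
#'
#' @param frequencies Positive clone frequencies summing to 1 (tolerance
#'   1e-9).
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' clonality(rep(0.25, 4)) # 0
#' clonality(1)            # 1
clonality <- function(frequencies) {
  if (length(frequencies) < 1L) stop("need at least one clone")
  if (any(frequencies <= 0)) stop("frequencies must be strictly positive")
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (tolerance 1e-9)")
  }
  r <- length(frequencies)
  if (r == 1L) return(1)
  h <- -sum(frequencies * log(frequencies))
  1 - h / log(r)
}

#' Normalized TCRB expression
#'
#' Reads mapped to the TCRB region per million total reads, comparable in
#' scale to CDR3 RPM.
#'
#' @param region_read_count Reads mapped to the TCRB region.
#' @param total_reads Total reads sequenced (> 0).
#' @return `region_read_count / total_reads * 1e6`.
#' @export
tcrb_expression <- function(region_read_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  region_read_count / total_reads * 1e6
}

#' DNA/RNA CDR3 concordance classes
#'
#' Classifies each sample with both a DNA and an RNA row as `D-R-`, `D+R-`,
#' `D-R+` or `D+R+` according to whether CDR3 reads were found in each
#' source. Samples missing one source are skipped with a warning.
#'
#' @param cohort A `CohortTable` with DNA and RNA rows.
#' @return A data.frame with `sample_id`, `dna_rpm`, `rna_rpm`, `class`.
#' @export
classify_dna_rna <- function(cohort) {
  ids <- unique(cohort$sample_id)
  dna <- cohort[cohort$source == "DNA", ]
  rna <- cohort[cohort$source == "RNA", ]
  have <- ids[ids %in% dna$sample_id & ids %in% rna$sample_id]
  missing <- setdiff(ids, have)
  if (length(missing)) {
    warning("skipping samples without both DNA and RNA rows: ",
            paste(missing, collapse = ", "))
  }
  if (!length(have)) {
    return(data.frame(sample_id = character(0), dna_rpm = numeric(0),
                      rna_rpm = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  d <- dna$cdr3_rpm[match(have, dna$sample_id)]
  r <- rna$cdr3_rpm[match(have, rna$sample_id)]
  data.frame(
    sample_id = have, dna_rpm = d, rna_rpm = r,
    class = paste0(ifelse(d > 0, "D+", "D-"), ifelse(r > 0, "R+", "R-")),
    stringsAsFactors = FALSE
  )
}

#' Clonotypes shared between two or more samples
#'
#' Exact-match grouping on the chosen clonotype key: amino-acid CDR3 by
#' default (convergent recombination makes amino-acid identity the usual
#' cross-sample unit; only productive clonotypes carry one) or nucleotide
#' CDR3.
#'
#' @param repertoires A list of `SampleRepertoire` objects (>= 2).
#' @param key `"aa"` (default) or `"nt"`.
#' @return A data.frame (`clonotype`, `n_samples`, `sample_ids`
#'   list-column) restricted to clonotypes seen in >= 2 samples, sorted by
#'   descending sample count then key.
#' @export
shared_clonotypes <- function(repertoires, key = c("aa", "nt")) {
  key <- match.arg(key)
  if (length(repertoires) < 2L) stop("need at least two repertoires")
  col <- if (key == "aa") "cdr3_aa" else "cdr3_nt"
  long <- do.call(rbind, lapply(repertoires, function(rep) {
    cl <- rep$clonotypes
    val <- cl[[col]]
    val <- unique(val[nzchar(val)])
    if (!length(val)) return(NULL)
    data.frame(sample_id = rep$sample_id, clonotype = val,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(clonotype = character(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
  empty$sample_ids <- list()
  if (is.null(long) || nrow(long) == 0L) return(empty)
  grp <- split(long$sample_id, long$clonotype)
  grp <- lapply(grp, unique)
  grp <- grp[vapply(grp, length, 0L) >= 2L]
  if (!length(grp)) return(empty)
  out <- data.frame(
    clonotype = names(grp),
    n_samples = vapply(grp, length, 0L),
    stringsAsFactors = FALSE
  )
  out$sample_ids <- unname(grp)
  out <- out[order(-out$n_samples, out$clonotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
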