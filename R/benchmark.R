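# Multi-detector comparison: overlap statistics across clonotype tables
# from several CDR3 detection tools, read-id level matching of calls, and
# comparison of a shallow exome repertoire against a deep-repertoire
# clonotype list.

#' Path to the packaged OX1285 tool-comparison fixture
#'
#' Per-clone read counts from three CDR3 detection tools (ClonotypeR,
#' IMSEQ, MiTCR) on one breast tumor exome, with deep-repertoire
#' abundances where available. Rescued out-of-frame evidence is encoded as
#' `>0` (present, count unknown); absent deep abundance as `NA`.
#'
#' @return The fixture path.
#' @export
table1_path <- function() {
  system.file("extdata", "table1_ox1285.tsv", package = "idnaseq",
              mustWork = TRUE)
}

#' Read a per-tool clonotype table
#'
#' Expected columns: `clone_id`, one integer-or-`>0` column per tool, and
#' `deep_abundance_pct` (numeric or NA). Lines starting with `#` are
#' comments.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return A data.frame of class `ToolClonotypeTable`; tool columns stay
#'   character so the `>0` rescued marker survives.
#' @export
read_tool_table <- function(path = table1_path()) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"clone_id" %in% names(df) || !"deep_abundance_pct" %in% names(df)) {
    stop("tool table needs clone_id and deep_abundance_pct columns")
  }
  if (anyDuplicated(df$clone_id)) stop("clone_id values must be unique")
  df$deep_abundance_pct <- suppressWarnings(as.numeric(df$deep_abundance_pct))
  tools <- setdiff(names(df), c("clone_id", "deep_abundance_pct"))
  if (!length(tools)) stop("tool table has no tool columns")
  det_any <- Reduce(`|`, lapply(df[tools], function(x) {
    x == ">0" | suppressWarnings(as.integer(x)) >= 1L
  }))
  if (!all(det_any)) {
    stop("rows without any tool evidence: ",
         paste(df$clone_id[!det_any], collapse = ", "))
  }
  class(df) <- c("ToolClonotypeTable", class(df))
  df
}

#' Per-tool detection matrix under a rescued policy
#' @noRd
detection_matrix <- function(table, rescued_policy) {
  tools <- setdiff(names(table), c("clone_id", "deep_abundance_pct"))
  det <- vapply(tools, function(t) {
    x <- table[[t]]
    n <- suppressWarnings(as.integer(x))
    (!is.na(n) & n >= 1L) | (x == ">0" & rescued_policy == "count")
  }, logical(nrow(table)))
  det <- matrix(det, nrow = nrow(table),
                dimnames = list(table$clone_id, tools))
  det
}

#' Overlap statistics across CDR3 detection tools
#'
#' A tool "detects" a clone when its integer read count is at least 1, or
#' when its evidence is the rescued marker `>0` and `rescued_policy` is
#' `"count"`. From that detection relation: per-tool detected counts, the
#' union, the clones present in the deep repertoire, each tool's in-deep
#' overlap fraction (the informal "sensitivity"), each tool's
#' shared-with-another-tool fraction (the informal "specificity"), and the
#' number of clones detected by two or more tools.
#'
#' @param table A `ToolClonotypeTable`.
#' @param rescued_policy `"count"` (rescued evidence counts as detection)
#'   or `"ignore"`.
#' @return An object of class `OverlapStats`: list with `per_tool`,
#'   `union`, `in_deep`, `in_deep_fraction`, `multi_tool_fraction`,
#'   `multi_tool_count`, `policy`.
#' @export
overlap_stats <- function(table, rescued_policy = c("count", "ignore")) {
  rescued_policy <- match.arg(rescued_policy)
  det <- detection_matrix(table, rescued_policy)
  in_deep_row <- !is.na(table$deep_abundance_pct)
  per_tool <- colSums(det)
  n_tools_per_clone <- rowSums(det)
  in_deep_frac <- vapply(colnames(det), function(t) {
    if (per_tool[t] == 0L) return(NA_real_)
    sum(det[, t] & in_deep_row) / per_tool[t]
  }, 0)
  multi_frac <- vapply(colnames(det), function(t) {
    if (per_tool[t] == 0L) return(NA_real_)
    others <- n_tools_per_clone - det[, t]
    sum(det[, t] & others >= 1L) / per_tool[t]
  }, 0)
  structure(
    list(
      per_tool = per_tool,
      union = sum(n_tools_per_clone >= 1L),
      in_deep = sum(n_tools_per_clone >= 1L & in_deep_row),
      in_deep_fraction = in_deep_frac,
      multi_tool_fraction = multi_frac,
      multi_tool_count = sum(n_tools_per_clone >= 2L),
      policy = rescued_policy
    ),
    class = "OverlapStats"
  )
}

#' @export
print.OverlapStats <- function(x, ...) {
  cat("OverlapStats (rescued policy:", x$policy, ")\n")
  cat("  per tool: ", paste(names(x$per_tool), x$per_tool, sep = "=",
                            collapse = "  "), "\n")
  cat(sprintf("  union %d | in deep repertoire %d | detected by >=2 tools %d\n",
              x$union, x$in_deep, x$multi_tool_count))
  for (t in names(x$per_tool)) {
    cat(sprintf("  %s: in-deep %.0f%%, shared-with-another-tool %.0f%%\n",
                t, 100 * x$in_deep_fraction[t], 100 * x$multi_tool_fraction[t]))
  }
  invisible(x)
}

#' Match CDR3 calls from two detectors at read-id level
#'
#' Calls with read ids are matched on id equality. For calls lacking ids
#' (some tools do not report them), the read id is recovered by exact
#' substring matching of the call's CDR3 against the candidate read
#' sequences, both strands; calls matching more than one read (or reads
#' matching more than one call) are reported as ambiguous, never silently
#' assigned.
#'
#' @param calls_a,calls_b Data.frames of calls (columns `read_id`,
#'   `cdr3_nt`; `read_id` may be NA in `calls_b`).
#' @param reads A `CandidateReadSet` used for sequence recovery.
#' @return A list: `matched` (data.frame of read ids found in both),
#'   `a_only`, `b_only` (read-id vectors), `ambiguous` (data.frame
#'   cdr3_nt / candidate read ids).
#' @export
match_read_ids <- function(calls_a, calls_b, reads) {
  recover <- function(calls) {
    ids <- calls$read_id
    amb <- list()
    need <- which(is.na(ids) | !nzchar(ids))
    for (i in need) {
      cdr3 <- calls$cdr3_nt[i]
      hit <- grepl(cdr3, reads$reads$seq, fixed = TRUE) |
        grepl(revcomp(cdr3), reads$reads$seq, fixed = TRUE)
      n <- sum(hit)
      if (n == 1L) {
        ids[i] <- reads$reads$read_id[hit]
      } else if (n >= 2L) {
        amb[[length(amb) + 1L]] <- data.frame(
          cdr3_nt = cdr3,
          candidate_reads = paste(reads$reads$read_id[hit], collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
    list(ids = ids, ambiguous = amb)
  }
  ra <- recover(calls_a)
  rb <- recover(calls_b)
  ia <- ra$ids[!is.na(ra$ids) & nzchar(ra$ids)]
  ib <- rb$ids[!is.na(rb$ids) & nzchar(rb$ids)]
  matched <- intersect(ia, ib)
  amb <- c(ra$ambiguous, rb$ambiguous)
  list(
    matched = data.frame(read_id = matched, stringsAsFactors = FALSE),
    a_only = setdiff(ia, ib),
    b_only = setdiff(ib, ia),
    ambiguous = if (length(amb)) do.call(rbind, amb) else
      data.frame(cdr3_nt = character(0), candidate_reads = character(0),
                 stringsAsFactors = FALSE)
  )
}

#' Compare an exome repertoire with a deep-repertoire clonotype list
#'
#' @param repertoire A non-empty `SampleRepertoire`.
#' @param deep A data.frame with a clonotype column (`cdr3`) and optional
#'   `abundance`.
#' @param key Clonotype key: `"nt"` (default, within-sample identity) or
#'   `"aa"`.
#' @return A list: `fraction` of exome clonotypes present in the deep
#'   list, and `annotation` (per-clonotype `in_deep` flag plus deep
#'   abundance).
#' @export
compare_to_deep <- function(repertoire, deep, key = c("nt", "aa")) {
  key <- match.arg(key)
  cl <- repertoire$clonotypes
  if (nrow(cl) == 0L) stop("empty repertoire")
  val <- if (key == "nt") cl$cdr3_nt else cl$cdr3_aa
  m <- match(val, deep$cdr3)
  ann <- data.frame(
    clonotype = val, in_deep = !is.na(m),
    deep_abundance = if ("abundance" %in% names(deep)) deep$abundance[m] else NA,
    stringsAsFactors = FALSE
  )
  list(fraction = mean(ann$in_deep), annotation = ann)
}
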