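test_that("align_segment agrees with an exhaustive ungapped oracle", {
  ref <- fixed_reference()
  params <- detect_params()
  v_seq <- ref$segments$seq[ref$segments$id == "TRBV-A"]

  # identity: the segment itself aligns full length, zero mismatches
  hit <- align_segment(v_seq, ref, "V", params)
  expect_equal(hit$id, "TRBV-A")
  expect_equal(hit$score, nchar(v_seq))
  expect_equal(hit$mismatches, 0L)
  expect_equal(c(hit$read_start, hit$read_end), c(1L, nchar(v_seq)))
  expect_equal(c(hit$seg_start, hit$seg_end), c(1L, nchar(v_seq)))

  # two substitutions in 60 aligned bases: oracle says 56, so do we
  long_v <- paste0(v_seq, "TCCGGAATCGTTGACCTGAAGGTCCAA")  # 60 nt segment
  ref60 <- reference_set(list(
    germline_segment("V60", "V", long_v, 27),
    germline_segment("TRBJ-A", "J", "CAACTCTTTGGCGGCGGAACCTTGGA", 6)
  ))
  read60 <- long_v
  substr(read60, 5, 5) <- chartr("ACGT", "TGAC", substr(read60, 5, 5))
  substr(read60, 45, 45) <- chartr("ACGT", "TGAC", substr(read60, 45, 45))
  hit60 <- align_segment(read60, ref60, "V", params)
  expect_equal(hit60$score, 56L)
  expect_equal(hit60$mismatches, 2L)
  expect_equal(
    hit60$score,
    oracle_best_ungapped(read60, long_v, params$min_v_match,
                         params$max_mismatch_rate)
  )

  # random non-TCR sequence with no shared seed k-mer: no hit
  rnd <- withr::with_seed(42, paste(sample(c("A", "C", "G", "T"), 80,
                                           replace = TRUE), collapse = ""))
  expect_null(align_segment(rnd, ref, "J", params))
})

test_that("oracle and aligner agree on randomized mutated segments", {
  ref <- fixed_reference()
  params <- detect_params()
  share_seed <- function(a, b, k = 12L) {
    ka <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
    kb <- substring(b, 1:(nchar(b) - k + 1), k:nchar(b))
    any(ka %in% kb)
  }
  withr::with_seed(7, {
    for (rep in 1:12) {
      row <- ref$segments[sample.int(4, 1), ]
      read <- row$seq
      n_mut <- sample(0:2, 1)
      if (n_mut > 0) {
        pos <- sample.int(nchar(read), n_mut)
        for (p in pos) {
          substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(read, p, p)), 1)
        }
      }
      hit <- align_segment(read, ref, row$class, params)
      want <- oracle_best_ungapped(
        read, row$seq,
        if (row$class == "V") params$min_v_match else params$min_j_match,
        params$max_mismatch_rate
      )
      if (is.null(hit)) {
        # the seed-and-extend path needs a shared k-mer; the oracle does not
        expect_true(is.null(want) || !share_seed(read, row$seq))
      } else {
        expect_gte(hit$score, want)  # another segment may also score higher
      }
    }
  })
})

test_that("call_cdr3 extracts the anchored junction", {
  ref <- fixed_reference()
  params <- detect_params()
  r <- junction_read(ref)  # V(30) + GCCAGCAGC + J(20)
  call <- call_cdr3(r$full_nt, ref, params, read_id = "r1")
  expect_s3_class(call, "Cdr3Call")
  expect_equal(call$cdr3_nt, "TGTGCCAGCAGCTTT")
  expect_equal(call$cdr3_aa, "CASSF")
  expect_equal(call$v_id, "TRBV-A")
  expect_equal(call$j_id, "TRBJ-A")
  expect_true(call$productive)
  expect_false(call$rescued)

  # reverse-complemented read gives the identical call
  rc_call <- call_cdr3(revcomp(r$full_nt), ref, params, read_id = "r1")
  expect_equal(rc_call$cdr3_nt, call$cdr3_nt)
  expect_equal(rc_call$v_id, call$v_id)

  # germline V only: no junction
  expect_null(call_cdr3(ref$segments$seq[1], ref, params))

  # out-of-frame junction only surfaces under rescue
  bad <- junction_read(ref, insert = "GCCAGCAGCGGGGG")  # 14 nt insert
  expect_null(call_cdr3(bad$full_nt, ref, params))
  resc <- call_cdr3(bad$full_nt, ref,
                    detect_params(rescue_out_of_frame = TRUE))
  expect_false(resc$productive)
  expect_true(resc$rescued)
  expect_equal(resc$cdr3_aa, "")

  # reads shorter than the combined flank minimum are never called
  expect_null(call_cdr3(strrep("A", 20), ref, params))
})

test_that("aggregate_clonotypes groups and collapses errors", {
  mk <- function(cdr3, id) data.frame(
    read_id = id, v_id = "V1", j_id = "J1", cdr3_nt = cdr3,
    cdr3_aa = "", productive = TRUE, rescued = FALSE,
    v_score = 30L, j_score = 12L, stringsAsFactors = FALSE
  )
  calls <- lapply(1:3, function(i) mk("TGTGCCTTT", paste0("r", i)))
  out <- aggregate_clonotypes(calls)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_count, 3L)
  expect_setequal(out$read_ids[[1]], c("r1", "r2", "r3"))

  # singleton at Hamming distance 1 of a 5-read clonotype merges in
  calls2 <- c(
    lapply(1:5, function(i) mk("TGTGCCAAATTT", paste0("a", i))),
    list(mk("TGTGCCAACTTT", "b1"))
  )
  out2 <- aggregate_clonotypes(calls2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$read_count, 6L)
  expect_true("b1" %in% out2$read_ids[[1]])

  # two singletons: no >=2-read sink, no merge
  out3 <- aggregate_clonotypes(list(mk("TGTGCCAAATTT", "a"),
                                    mk("TGTGCCAACTTT", "b")))
  expect_equal(nrow(out3), 2L)

  # collapse disabled keeps the singleton separate
  out4 <- aggregate_clonotypes(calls2, detect_params(error_collapse = FALSE))
  expect_equal(nrow(out4), 2L)

  # read-count conservation through collapse
  expect_equal(sum(out2$read_count), length(calls2))
})

test_that("detect_sample normalizes to reads per million", {
  ref <- fixed_reference()
  empty <- structure(
    list(sample_id = "s", reads = data.frame(
      read_id = character(0), seq = character(0), source = character(0),
      clipped = logical(0)
    ), total_reads = 100),
    class = "CandidateReadSet"
  )
  rep0 <- detect_sample(empty, ref)
  expect_equal(nrow(rep0$clonotypes), 0L)
  expect_equal(rep0$cdr3_rpm, 0)

  # 18 junction reads over 205e6 total reads: 0.09 RPM to two decimals
  r <- junction_read(ref)
  cands <- structure(
    list(sample_id = "OX", reads = data.frame(
      read_id = sprintf("r%02d", 1:18), seq = rep(r$full_nt, 18),
      source = "unmapped", clipped = NA, stringsAsFactors = FALSE
    ), total_reads = 205e6),
    class = "CandidateReadSet"
  )
  rep <- detect_sample(cands, ref)
  expect_equal(rep$cdr3_read_count, 18L)
  expect_equal(round(rep$cdr3_rpm, 2), 0.09)

  expect_error(detect_sample(structure(list(total_reads = 0),
                                       class = "CandidateReadSet"), ref),
               "positive")
})

test_that("repertoire is invariant to read order and strand", {
  ref <- make_toy_reference(3, 2, seed = 14)
  mix <- sample_mixture(3, 1, ref, seed = 14)
  sim <- simulate_reads(mix, sim_config(0.4, 60, error_rate = 0, seed = 3,
                                        exome_len = 2e4), ref)
  cand <- sim_candidates(sim)
  base <- detect_sample(cand, ref)
  expect_gt(base$cdr3_read_count, 0L)

  perm <- cand
  perm$reads <- perm$reads[rev(seq_len(nrow(perm$reads))), ]
  expect_equal(detect_sample(perm, ref)$clonotypes[, 1:6],
               base$clonotypes[, 1:6])

  flipped <- cand
  flipped$reads$seq <- revcomp(flipped$reads$seq)
  expect_equal(detect_sample(flipped, ref)$clonotypes[, 1:6],
               base$clonotypes[, 1:6])

  # every called clonotype exists in the simulation truth
  truth <- vapply(mix$clones, `[[`, "", "cdr3_nt")
  expect_true(all(base$clonotypes$cdr3_nt %in% truth))
})

test_that("repertoire TSV round-trips", {
  ref <- fixed_reference()
  r <- junction_read(ref)
  cands <- structure(
    list(sample_id = "s1", reads = data.frame(
      read_id = c("x1", "x2"), seq = rep(r$full_nt, 2),
      source = "unmapped", clipped = NA, stringsAsFactors = FALSE
    ), total_reads = 1e6),
    class = "CandidateReadSet"
  )
  rep <- detect_sample(cands, ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(rep, path)
  back <- read_repertoire(path)
  expect_equal(back$sample_id, "s1")
  expect_equal(back$cdr3_rpm, rep$cdr3_rpm)
  expect_equal(back$clonotypes$cdr3_nt, rep$clonotypes$cdr3_nt)
  expect_equal(back$clonotypes$read_count, rep$clonotypes$read_count)
})
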