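toy_junction_ref <- function() {
  reference_set(list(
    germline_segment("V1", "V", "AAATGT", 3),
    germline_segment("J1", "J", "TTTGGCGGCGGA", 0)
  ))
}

test_that("rearrange assembles the junction and scores productivity", {
  ref <- toy_junction_ref()
  r <- rearrange(rearrangement_spec("V1", "J1", n_insert = "GCCAGCAGC"), ref)
  expect_equal(r$full_nt, "AAATGTGCCAGCAGCTTTGGCGGCGGA")
  expect_equal(r$cdr3_nt, "TGTGCCAGCAGCTTT")
  expect_equal(r$cdr3_aa, "CASSF")
  expect_true(r$productive)

  # 14 nt junction -> out of frame
  r2 <- rearrange(rearrangement_spec("V1", "J1", n_insert = "GCCAGCAG"), ref)
  expect_equal(nchar(r2$cdr3_nt), 14L)
  expect_false(r2$productive)

  # in-frame stop codon
  r3 <- rearrange(rearrangement_spec("V1", "J1", n_insert = "TAAGCCAGC"), ref)
  expect_false(r3$productive)

  # trims may not consume anchors
  expect_error(rearrange(rearrangement_spec("V1", "J1", v_trim = 1), ref),
               "consumes the V anchor")
  expect_error(rearrange(rearrangement_spec("V1", "J1", j_trim = 1), ref),
               "consumes the J anchor")
})

test_that("trimmed junctions keep CDR3 coordinates consistent", {
  ref <- fixed_reference()
  r <- junction_read(ref, v_trim = 2, j_trim = 4, insert = "GGGACT")
  expect_equal(substr(r$full_nt, r$cdr3_start, r$cdr3_end), r$cdr3_nt)
  expect_true(startsWith(r$cdr3_nt, "TGT"))
  expect_true(endsWith(substr(r$cdr3_nt, 1, nchar(r$cdr3_nt)), "TTT"))
})

test_that("sample_mixture draws power-law mixtures deterministically", {
  ref <- make_toy_reference(4, 3, seed = 2)
  one <- sample_mixture(1, 1, ref, seed = 5)
  expect_equal(one$freq, 1)

  unif <- sample_mixture(4, 0, ref, seed = 5)
  expect_equal(unif$freq, rep(0.25, 4))

  zipf <- sample_mixture(10, 1, ref, seed = 5)
  h10 <- sum(1 / (1:10))
  expect_equal(zipf$freq, (1 / (1:10)) / h10)
  expect_equal(zipf$freq[1], 0.341417, tolerance = 1e-6)

  again <- sample_mixture(10, 1, ref, seed = 5)
  expect_identical(
    vapply(zipf$clones, `[[`, "", "cdr3_nt"),
    vapply(again$clones, `[[`, "", "cdr3_nt")
  )
  expect_true(all(vapply(zipf$clones, `[[`, TRUE, "productive")))
  expect_error(sample_mixture(3, -1, ref, seed = 1), "alpha")
})

test_that("simulate_reads respects the T-cell fraction and is seeded", {
  ref <- make_toy_reference(3, 2, seed = 4)
  mix <- sample_mixture(3, 1, ref, seed = 4)

  none <- simulate_reads(mix, sim_config(0, 10, error_rate = 0, seed = 1,
                                         exome_len = 2e4), ref)
  expect_equal(sum(none$reads$source == "tcell"), 0L)
  expect_equal(sum(none$manifest$origin != "background"), 0L)
  expect_equal(none$n_total, round(2e4 * 10 / 100 / 0.8))

  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  cfg <- sim_config(0.4, 25, error_rate = 0.001, seed = 99, exome_len = 2e4)
  simulate_reads(mix, cfg, ref, fastq = fq1)
  simulate_reads(mix, cfg, ref, fastq = fq2)
  expect_identical(readLines(fq1), readLines(fq2))
})

test_that("spanning fraction of T-cell reads follows read geometry", {
  ref <- toy_junction_ref()
  # one clone, 15 nt CDR3 inside a 27 nt template
  mix <- sample_mixture(1, 0, ref, seed = 1)
  mix$clones[[1]] <- rearrange(
    rearrangement_spec("V1", "J1", n_insert = "GCCAGCAGC"), ref
  )
  rl <- 100L
  clone <- mix$clones[[1]]
  sim <- simulate_reads(
    mix, sim_config(0.5, 400, read_length = rl, error_rate = 0, seed = 8,
                    exome_len = 5e4), ref
  )
  t_reads <- sim$manifest[sim$manifest$origin != "background", ]
  expect_gt(nrow(t_reads), 200)
  p_hat <- mean(t_reads$spans_cdr3)
  p_geo <- (rl - nchar(clone$cdr3_nt) + 1) /
    (nchar(clone$full_nt) + rl - 1)
  se <- sqrt(p_geo * (1 - p_geo) / nrow(t_reads))
  expect_lt(abs(p_hat - p_geo), 4 * se)
})

test_that("no background read contains a clone CDR3 and outputs agree", {
  ref <- make_toy_reference(3, 2, seed = 6)
  mix <- sample_mixture(3, 1, ref, seed = 6)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "sim.fastq")
  bam <- file.path(dir, "sim.bam")
  cfg <- sim_config(0.3, 40, error_rate = 0, seed = 21, exome_len = 2e4)
  sim <- simulate_reads(mix, cfg, ref, fastq = fq, bam = bam)

  bg <- sim$reads$seq[sim$reads$source != "tcell"]
  for (cl in mix$clones) {
    expect_false(any(grepl(cl$cdr3_nt, bg, fixed = TRUE)))
  }

  # FASTQ and BAM contain the same reads (ids and original sequences)
  fq_seqs <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_setequal(names(fq_seqs), sim$reads$read_id)
  cand <- harvest(bam, window = ref$locus_window, denominator = "primary")
  expect_equal(cand$total_reads, nrow(sim$reads))
  in_bam <- cand$reads
  key <- setNames(sim$reads$seq, sim$reads$read_id)
  expect_true(all(in_bam$seq == key[in_bam$read_id]))
})

test_that("manifest clone counts converge to mixture frequencies", {
  ref <- make_toy_reference(4, 3, seed = 9)
  mix <- sample_mixture(5, 1, ref, seed = 9)
  pvals <- vapply(1:3, function(s) {
    sim <- simulate_reads(
      mix, sim_config(0.6, 300, error_rate = 0, seed = 30 + s,
                      exome_len = 2e4), ref
    )
    counts <- table(factor(
      sim$manifest$clone_id[sim$manifest$origin != "background"],
      levels = mix$clone_id
    ))
    suppressWarnings(stats::chisq.test(counts, p = mix$freq)$p.value)
  }, 0)
  expect_true(all(pvals > 0.01))
})

test_that("short reads trigger the unspannable-CDR3 warning", {
  ref <- make_toy_reference(3, 2, seed = 12)
  mix <- sample_mixture(2, 1, ref, seed = 12)
  long_cdr3 <- max(vapply(mix$clones, function(r) nchar(r$cdr3_nt), 0L))
  expect_lt(long_cdr3, 50)  # toy junctions are short; force the edge
  mix$clones[[1]]$cdr3_nt <- strrep("A", 60)
  expect_warning(
    simulate_reads(mix, sim_config(0.1, 5, read_length = 50, error_rate = 0,
                                   seed = 1, exome_len = 1e4), ref),
    "cannot be fully spanned"
  )
  expect_error(
    simulate_reads(structure(list(clones = list(), freq = numeric(0)),
                             class = "CloneMixture"),
                   sim_config(0.1, 5, seed = 1, exome_len = 1e4), ref),
    "empty"
  )
})
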