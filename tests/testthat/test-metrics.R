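test_that("iDNA deciles: zeros score 0, positives cut into ten rank bins", {
  coh <- cohort_table(
    sample_id = sprintf("s%02d", 1:25), source = rep("DNA", 25),
    cdr3_rpm = c(rep(0, 5), 1:20), n_clonotypes = c(rep(0, 5), rep(1, 20))
  )
  sc <- idna_scores(coh, "DNA")
  expect_equal(sc$score[sc$cdr3_rpm == 0], rep(0L, 5))
  # 20 positive rpms 1..20 -> pairs (1,2)=1, (3,4)=2, ..., (19,20)=10
  pos <- sc[sc$cdr3_rpm > 0, ]
  pos <- pos[order(pos$cdr3_rpm), ]
  expect_equal(pos$score, rep(1:10, each = 2))
  expect_equal(pos$score[which.max(pos$cdr3_rpm)], 10L)

  all0 <- cohort_table("a", "DNA", 0, 0)
  expect_equal(idna_scores(all0, "DNA")$score, 0L)

  expect_error(idna_scores(coh, "RNA"), "no cohort rows")
  expect_warning(
    idna_scores(cohort_table(c("a", "b"), "DNA", c(1, 2), c(1, 1)), "DNA"),
    "fewer than 10"
  )
})

test_that("decile invariants hold on randomized cohorts", {
  for (s in 1:10) {
    rpm <- withr::with_seed(1000 + s, {
      n <- sample(15:60, 1)
      r <- round(rexp(n, 2), 3)            # ties likely after rounding
      r[sample.int(n, sample.int(n - 12, 1))] <- 0
      r
    })
    coh <- cohort_table(
      sample_id = paste0("t", seq_along(rpm)), source = "DNA",
      cdr3_rpm = rpm, n_clonotypes = as.integer(rpm > 0)
    )
    sc <- suppressWarnings(idna_scores(coh, "DNA"))
    expect_true(all((sc$score == 0) == (sc$cdr3_rpm == 0)))
    ord <- order(sc$cdr3_rpm)
    expect_true(all(diff(sc$score[ord]) >= 0))   # monotone in rpm
    expect_true(all(sc$score >= 0 & sc$score <= 10))
    pos <- sc$score[sc$cdr3_rpm > 0]
    if (length(pos) >= 10 && !anyDuplicated(sc$cdr3_rpm[sc$cdr3_rpm > 0])) {
      expect_lte(diff(range(table(factor(pos, levels = 1:10)))), 1)
    }
  }
})

test_that("diversity ratio is the exact clonotype/rpm quotient", {
  expect_equal(diversity_ratio(1, 1.0), 1.0)
  expect_equal(diversity_ratio(5, 0.5), 10.0)
  expect_error(diversity_ratio(3, 0), "undefined")
  # the cohort invariant makes (0 clonotypes, positive rpm) unrepresentable
  expect_error(cohort_table("a", "DNA", 0.2, 0), "zero exactly when")
})

test_that("clonality is 1 - normalized Shannon entropy", {
  expect_equal(clonality(rep(0.25, 4)), 0)
  expect_equal(clonality(1), 1)
  # hand computation: H = 0.9404480, 1 - H/ln(4) = 0.3216102
  f <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(clonality(f), 0.3216102, tolerance = 1e-6)
  # cross-check against an independent entropy implementation
  expect_equal(clonality(f), 1 - as.numeric(vegan::diversity(f)) / log(4),
               tolerance = 1e-12)

  # permutation invariance and concentration monotonicity
  expect_equal(clonality(c(0.1, 0.7, 0.1, 0.1)), clonality(f))
  expect_gt(clonality(c(0.5, 0.25, 0.25)),
            clonality(c(1, 1, 1) / 3))
  expect_equal(clonality(c(0.5, 0.5)), 0)

  expect_error(clonality(c(0.5, 0.4)), "sum to 1")
  expect_error(clonality(c(1.2, -0.2)), "positive")
})

test_that("clonality strictly increases as mass concentrates at fixed R", {
  # transfer mass from a smaller clone to a larger one (entropy is strictly
  # Schur-concave, so clonality strictly increases)
  for (s in 1:5) {
    f <- withr::with_seed(50 + s, {
      x <- rexp(6); sort(x / sum(x), decreasing = TRUE)
    })
    eps <- f[6] / 2
    g <- f; g[1] <- g[1] + eps; g[6] <- g[6] - eps
    expect_gt(clonality(g), clonality(f))
  }
})

test_that("TCRB expression normalizes per million reads", {
  expect_equal(tcrb_expression(0, 1e6), 0)
  expect_equal(tcrb_expression(50, 1e6), 50)
  expect_equal(tcrb_expression(18, 205e6), 0.0878, tolerance = 1e-3)
  expect_error(tcrb_expression(1, 0), "positive")
})

test_that("DNA/RNA concordance classes follow presence in each source", {
  coh <- cohort_table(
    sample_id = c("a", "a", "b", "b", "c", "c", "d", "d", "lone"),
    source = c("DNA", "RNA", "DNA", "RNA", "DNA", "RNA", "DNA", "RNA", "DNA"),
    cdr3_rpm = c(0, 0, 0.1, 0, 0, 1.4, 0.1, 2.3, 1),
    n_clonotypes = c(0, 0, 1, 0, 0, 3, 1, 4, 1)
  )
  expect_warning(cls <- classify_dna_rna(coh), "lone")
  got <- setNames(cls$class, cls$sample_id)
  expect_equal(got[["a"]], "D-R-")
  expect_equal(got[["b"]], "D+R-")
  expect_equal(got[["c"]], "D-R+")
  expect_equal(got[["d"]], "D+R+")
})

test_that("shared clonotypes group across samples, nt sharing implies aa", {
  mk_rep <- function(id, aa, nt) structure(
    list(sample_id = id, clonotypes = data.frame(
      cdr3_nt = nt, cdr3_aa = aa, v_id = "V", j_id = "J",
      read_count = 1L, productive = TRUE, stringsAsFactors = FALSE
    ), cdr3_read_count = length(nt), total_reads = 1e6,
    cdr3_rpm = length(nt)),
    class = "SampleRepertoire"
  )
  # disjoint -> empty
  expect_equal(nrow(shared_clonotypes(list(
    mk_rep("s1", "CASSA", "TGTGCAA"), mk_rep("s2", "CASSB", "TGTGCCC")
  ))), 0L)

  # same aa in three samples, two different nt encodings
  reps <- list(
    mk_rep("s1", "CASSF", "TGTGCCAGCAGCTTT"),
    mk_rep("s2", "CASSF", "TGTGCCAGCAGCTTC"),
    mk_rep("s3", "CASSF", "TGTGCCAGCAGCTTT"),
    mk_rep("s4", "CASSX", "TGTGCCAGCAGCAAA")
  )
  aa <- shared_clonotypes(reps, key = "aa")
  expect_equal(aa$clonotype, "CASSF")
  expect_equal(aa$n_samples, 3L)
  expect_setequal(aa$sample_ids[[1]], c("s1", "s2", "s3"))

  nt <- shared_clonotypes(reps, key = "nt")
  expect_equal(nt$clonotype, "TGTGCCAGCAGCTTT")
  expect_setequal(nt$sample_ids[[1]], c("s1", "s3"))

  # nt-sharing sample sets are subsets of aa-sharing sample sets
  aa_map <- setNames(aa$sample_ids, aa$clonotype)
  for (k in seq_len(nrow(nt))) {
    aas <- unique(unlist(lapply(reps, function(r) {
      r$clonotypes$cdr3_aa[r$clonotypes$cdr3_nt == nt$clonotype[k]]
    })))
    expect_true(all(nt$sample_ids[[k]] %in% unlist(aa_map[aas])))
  }

  expect_error(shared_clonotypes(reps[1]), "at least two")
})
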