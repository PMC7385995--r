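# Independent full-matrix affine-gap dynamic programming (Gotoh), used
# only as an oracle for alignment scores.  A gap of length L costs
# |gap_open| + L * |gap_extend|, matching the package's convention.
gotoh_score <- function(a, b, scoring = align_scoring()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  go <- -abs(scoring$gap_open)
  ge <- -abs(scoring$gap_extend)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- go + ge * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- go + ge * (j - 1)
  sub <- function(x, y) {
    if (x %in% c("A", "C", "G", "T") && x == y) scoring$match else scoring$mismatch
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub(av[i - 1], bv[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + go + ge, X[i - 1, j] + ge)
      Y[i, j] <- max(M[i, j - 1] + go + ge, Y[i, j - 1] + ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

test_that("global alignment matches identities on worked examples", {
  expect_equal(global_align("ACGT", "ACGT")$identity, 1.0)
  expect_equal(global_align("ACGT", "ACGT")$score, 4 * align_scoring()$match)
  expect_equal(global_align("ACGT", "ACCT")$identity, 0.75)
  expect_error(global_align("", "ACGT"))
})

test_that("global alignment score equals the exhaustive DP oracle", {
  set.seed(42)
  for (i in 1:8) {
    a <- random_dna(sample(20:60, 1), gc = runif(1, 0.3, 0.6))
    b <- if (i %% 2 == 0) {
      random_dna(sample(20:60, 1), gc = 0.5)
    } else {
      # structurally related pair: mutate + delete a chunk
      paste0(substr(evolve(a, 0.1), 1, 15),
             substr(evolve(a, 0.1), 22, nchar(a)))
    }
    expect_equal(global_align(a, b)$score, gotoh_score(a, b),
                 info = paste("pair", i))
  }
})

test_that("global alignment score is invariant under argument swap", {
  set.seed(1)
  for (i in 1:5) {
    a <- random_dna(40)
    b <- random_dna(35)
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("seed-and-extend finds planted queries with clean hits", {
  set.seed(11)
  q <- random_dna(80, gc = 0.5)
  subj <- paste0(random_dna(300), q, random_dna(300))
  h <- seeded_local_align(q, subj, seed_len = 12)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$coverage_query, 1.0)
  expect_equal(h$s_start, 301L)
  expect_equal(h$strand, "+")
  # reverse-complement planting is found on the minus strand at the same
  # forward coordinates
  subj_rc <- paste0(random_dna(300), revcomp(q), random_dna(300))
  h2 <- seeded_local_align(q, subj_rc, seed_len = 12)
  expect_equal(h2$strand, "-")
  expect_equal(h2$s_start, 301L)
})

test_that("seed-and-extend tolerates divergence and reports sane fractions", {
  set.seed(12)
  q <- random_dna(200, gc = 0.5)
  q_mut <- evolve(q, 0.05)
  subj <- paste0(random_dna(200), q_mut, random_dna(200))
  h <- seeded_local_align(q, subj, seed_len = 12)
  expect_gte(nrow(h), 1L)
  expect_gte(h$identity[1], 0.90)
  expect_true(all(h$identity >= 0 & h$identity <= 1))
  expect_true(all(h$coverage_query >= 0 & h$coverage_query <= 1))
  # no shared 12-mer -> no hits
  expect_equal(nrow(seeded_local_align("ACGTACGTACGTACGT",
                                       strrep("C", 500), seed_len = 12)), 0L)
})

test_that("merged local hits never overlap on the subject", {
  set.seed(13)
  q <- random_dna(100)
  subj <- paste0(random_dna(150), q, random_dna(150), evolve(q, 0.08),
                 random_dna(150), revcomp(q), random_dna(150))
  h <- seeded_local_align(q, subj, seed_len = 12)
  expect_gte(nrow(h), 3L)
  ir <- IRanges::IRanges(h$s_start, h$s_end)
  expect_true(all(IRanges::countOverlaps(ir, ir) == 1L))
  expect_equal(h$score, sort(h$score, decreasing = TRUE))
})

test_that("progressive MSA is lossless and handles indels", {
  msa <- progressive_msa(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_true(all(!grepl("-", msa$aligned)))
  # one deletion -> exactly one gap column
  msa2 <- progressive_msa(c(a = "ACGTTACGT", b = "ACGTACGT"))
  expect_equal(sum(strsplit(msa2$aligned[msa2$taxon == "b"], "")[[1]] == "-"), 1L)
  # ungapping reproduces the inputs in input order
  set.seed(3)
  seqs <- setNames(vapply(1:6, function(i) random_dna(sample(60:80, 1)), ""),
                   letters[1:6])
  msa3 <- progressive_msa(seqs)
  expect_equal(msa3$taxon, names(seqs))
  expect_equal(gsub("-", "", msa3$aligned), unname(seqs))
  expect_error(progressive_msa("ACGT"), "at least 2")
})

test_that("MSA of a diverged family stays close to its consensus", {
  set.seed(4)
  anc <- random_dna(300, gc = 0.35)
  seqs <- setNames(vapply(1:10, function(i) evolve(anc, 0.05), ""),
                   sprintf("s%d", 1:10))
  msa <- progressive_msa(seqs)
  cons <- mitescout:::consensus_row(msa)
  for (i in seq_len(nrow(msa))) {
    a <- strsplit(msa$aligned[i], "")[[1]]
    b <- strsplit(cons, "")[[1]]
    ok <- a != "-" & b != "-"
    expect_gte(mean(a[ok] == b[ok]), 0.90)
  }
})
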