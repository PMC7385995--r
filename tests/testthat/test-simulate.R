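test_that("genome simulation is deterministic and respects its knobs", {
  s1 <- simulate_genome(40000, gc = 0.5, n_genes = 5, seed = 91)
  s2 <- simulate_genome(40000, gc = 0.5, n_genes = 5, seed = 91)
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$genes, s2$genes)
  # gc = 1 leaves no A or T in the background
  s3 <- simulate_genome(10000, gc = 1, n_genes = 0, seed = 92)
  expect_false(grepl("[AT]", s3$genome$seq))
  expect_equal(nrow(s3$genes), 0L)
  # genes are non-overlapping with sorted in-bounds exons
  g <- s1$genes
  ir <- IRanges::IRanges(g$start, g$end)
  expect_true(all(IRanges::countOverlaps(ir, ir) == 1L))
  for (i in seq_len(nrow(g))) {
    ex <- g$exons[[i]]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start >= g$start[i] & ex$end <= g$end[i]))
  }
})

test_that("planted copies carry the designed structure and age model", {
  cfg <- mite_config()
  s <- small_sim()
  truth <- s$sim$truth
  expect_equal(nrow(truth), 10L)
  expect_equal(truth$true_k, 2 * cfg$substitution_rate_r * truth$true_T)
  gseq <- s$sim$genome$seq[[1]]
  for (i in seq_len(nrow(truth))) {
    expect_equal(substr(gseq, truth$start[i], truth$end[i]), truth$seq[i])
  }
  # undiverged copies equal the consensus and keep both TSD copies exact
  young <- truth[truth$true_T == 0, ]
  expect_gte(nrow(young), 1L)
  for (i in seq_len(nrow(young))) {
    expect_equal(young$seq[i], s$spec$consensus)
    expect_equal(substr(gseq, young$start[i] - 8L, young$start[i] - 1L),
                 young$tsd[i])
    expect_equal(substr(gseq, young$end[i] + 1L, young$end[i] + 8L),
                 young$tsd[i])
  }
})

test_that("realized divergence tracks the requested substitution rate", {
  set.seed(93)
  anc <- random_dna(670, gc = 0.3)
  k <- 0.052
  obs <- vapply(1:100, function(i) {
    mean(strsplit(evolve(anc, k), "")[[1]] != strsplit(anc, "")[[1]])
  }, 0)
  # expected observed divergence is slightly below k (multiple hits)
  expect_equal(mean(obs), 0.05, tolerance = 0.02)
})

test_that("genic bias places every copy within the genic window", {
  cfg <- mite_config()
  sim <- simulate_genome(150000, gc = 0.4, n_genes = 12, seed = 94)
  sp <- mite_plant_spec("fam", length = 400, tir_len = 12, tsd_len = 8,
                        n_copies = 15, genic_bias = 1,
                        ages = tibble::tibble(T_years = 0, weight = 1))
  sim <- plant_mites(sim, sp, cfg, seed = 95)
  calls <- classify_position(sim$truth, sim$genes, cfg)
  expect_true(all(calls$proximal))
})

test_that("excision restores the pre-insertion allele exactly", {
  cfg <- mite_config()
  pre <- simulate_genome(30000, gc = 0.4, n_genes = 0, seed = 96)
  sp <- mite_plant_spec("fam", length = 300, tir_len = 12, tsd_len = 8,
                        n_copies = 4,
                        ages = tibble::tibble(T_years = 0, weight = 1))
  post <- plant_mites(pre, sp, cfg, seed = 97)
  # removing every element (and one TSD copy each) reproduces the original
  restored <- excise(post$genome, post$truth)
  expect_identical(restored$seq, pre$genome$seq)
  expect_error(excise(restored, post$truth[1, ]), "does not match")
})

test_that("read simulation hits its coverage and error contracts", {
  g <- simulate_genome(50000, gc = 0.45, n_genes = 0, seed = 98)$genome
  reads <- simulate_reads(g, coverage = 5, read_len = 100, seed = 99)
  expect_equal(sum(nchar(reads$seq)), 5 * 50000, tolerance = 100 / (5 * 50000))
  # byte-identical under the same seed
  reads2 <- simulate_reads(g, coverage = 5, read_len = 100, seed = 99)
  expect_identical(reads, reads2)
  # error-free reads are exact (possibly reverse-complemented) substrings
  idx <- sample(nrow(reads), 20)
  for (i in idx) {
    r <- reads[i, ]
    sub <- substr(g$seq, r$start, r$start + 99L)
    expect_equal(if (r$strand == "+") r$seq else revcomp(r$seq), sub)
  }
  # with errors, divergence matches the requested rate
  readsE <- simulate_reads(g, coverage = 2, read_len = 100,
                           error_rate = 0.02, seed = 100)
  mm <- vapply(seq_len(200), function(i) {
    r <- readsE[i, ]
    sub <- substr(g$seq, r$start, r$start + 99L)
    s <- if (r$strand == "+") r$seq else revcomp(r$seq)
    mean(strsplit(s, "")[[1]] != strsplit(sub, "")[[1]])
  }, 0)
  expect_lt(abs(mean(mm) - 0.02), 0.005)
})

test_that("observed divergence regressed on true age recovers the clock rate", {
  cfg <- mite_config()
  r <- cfg$substitution_rate_r
  set.seed(103)
  anc <- random_dna(400, gc = 0.35)
  T_true <- rep(c(1e6, 2e6, 3e6, 5e6, 10e6), each = 100)
  k_hat <- vapply(T_true, function(Tt) {
    k2p_distance(anc, evolve(anc, 2 * r * Tt))$k
  }, 0)
  slope <- stats::coef(stats::lm(k_hat ~ T_true))[["T_true"]]
  expect_lt(abs(slope - 2 * r) / (2 * r), 0.10)
})

test_that("discovery scoring agrees with a brute-force matcher", {
  brute_eval <- function(predicted, truth, min_overlap = 0.8) {
    pairs <- expand.grid(p = seq_len(nrow(predicted)), t = seq_len(nrow(truth)))
    ow <- mapply(function(p, t) {
      if (predicted$seqid[p] != truth$seqid[t]) return(0L)
      w <- min(predicted$end[p], truth$end[t]) -
        max(predicted$start[p], truth$start[t]) + 1L
      lp <- predicted$end[p] - predicted$start[p] + 1L
      lt <- truth$end[t] - truth$start[t] + 1L
      if (w >= min_overlap * lp && w >= min_overlap * lt) w else 0L
    }, pairs$p, pairs$t)
    pairs <- pairs[ow > 0, ]
    ow <- ow[ow > 0]
    used_p <- used_t <- integer()
    n <- 0L
    for (i in order(-ow)) {
      if (!(pairs$p[i] %in% used_p) && !(pairs$t[i] %in% used_t)) {
        used_p <- c(used_p, pairs$p[i]); used_t <- c(used_t, pairs$t[i])
        n <- n + 1L
      }
    }
    n
  }
  set.seed(102)
  for (rep in 1:5) {
    truth <- tibble::tibble(
      seqid = "c",
      start = sort(sample(seq(1, 20000, by = 450), 12)),
      end = 0L)
    truth$end <- truth$start + sample(200:400, 12, replace = TRUE)
    predicted <- truth[sample(12, 9), ]
    predicted$start <- predicted$start + sample(-30:30, 9, replace = TRUE)
    predicted$end <- predicted$end + sample(-30:30, 9, replace = TRUE)
    predicted <- dplyr::bind_rows(
      predicted,
      tibble::tibble(seqid = "c", start = c(21000L, 25000L),
                     end = c(21300L, 25500L)))
    ev <- evaluate_discovery(predicted, truth)
    expect_equal(ev$n_matched, brute_eval(predicted, truth))
    expect_equal(ev$precision, ev$n_matched / nrow(predicted))
    expect_equal(ev$recall, ev$n_matched / nrow(truth))
  }
  # identical predictions and the empty-prediction convention
  t0 <- tibble::tibble(seqid = "c", start = c(100L, 900L), end = c(400L, 1300L))
  expect_equal(evaluate_discovery(t0, t0)$precision, 1)
  expect_equal(evaluate_discovery(t0, t0)$recall, 1)
  e0 <- evaluate_discovery(t0[0, ], t0)
  expect_equal(e0$precision, 0)
  expect_equal(e0$recall, 0)
  expect_false(e0$precision_defined)
})
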