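test_that("a planted element with hAT geometry is recovered exactly", {
  cfg <- mite_config()
  set.seed(61)
  sp <- mite_plant_spec("f1", length = 673, tir_len = 25, tsd_len = 8,
                        n_copies = 1, at_fraction = 0.70,
                        ages = tibble::tibble(T_years = 0, weight = 1))
  sim <- simulate_genome(20000, gc = 0.4, seed = 62)
  sim <- plant_mites(sim, sp, cfg, seed = 63)
  cands <- find_tir_candidates(sim$genome, cfg)
  hit <- cands[cands$start == sim$truth$start, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$end, sim$truth$end)
  expect_equal(hit$length, 673L)
  expect_equal(hit$tir_len, 25L)
  expect_equal(hit$tir_identity, 1.0)
  expect_equal(hit$tsd, sim$truth$tsd)
  expect_equal(nchar(hit$tsd), 8L)
})

test_that("the TIR length threshold excludes short-TIR elements", {
  cfg13 <- mite_config(min_tir_len = 13L)
  set.seed(64)
  sp <- mite_plant_spec("f1", length = 400, tir_len = 12, tsd_len = 8,
                        n_copies = 1,
                        ages = tibble::tibble(T_years = 0, weight = 1))
  sim <- simulate_genome(15000, gc = 0.5, seed = 65)
  sim <- plant_mites(sim, sp, mite_config(), seed = 66)
  cands <- find_tir_candidates(sim$genome, cfg13)
  expect_false(any(cands$start == sim$truth$start & cands$end == sim$truth$end))
  # with the default threshold of 10 it is found
  cands10 <- find_tir_candidates(sim$genome, mite_config())
  expect_true(any(cands10$start == sim$truth$start & cands10$end == sim$truth$end))
})

test_that("every emitted candidate satisfies the structural bounds", {
  s <- small_sim()
  cands <- find_tir_candidates(s$sim$genome, s$cfg)
  expect_true(all(cands$length >= s$cfg$min_element_len))
  expect_true(all(cands$length <= s$cfg$max_element_len))
  expect_true(all(cands$tir_len >= s$cfg$min_tir_len))
  expect_true(all(cands$tir_len <= s$cfg$max_tir_len))
  expect_true(all(cands$tir_identity >= s$cfg$tir_min_identity))
  expect_true(all(cands$at_fraction >= 0 & cands$at_fraction <= 1))
  tl <- cands$tsd_len[!is.na(cands$tsd_len)]
  expect_true(all(tl >= s$cfg$tsd_len_range[1] & tl <= s$cfg$tsd_len_range[2]))
  # candidates are mutually non-overlapping after resolution
  ir <- IRanges::IRanges(cands$start, cands$end)
  expect_true(all(IRanges::countOverlaps(ir, ir) == 1L))
})

test_that("TSD detection finds the longest exact flanking duplication", {
  el <- paste0("GGGCCC", strrep("ACGT", 30), "GGGCCC")
  flank <- "ACGTACGT"  # 8 bp planted duplication
  g <- tibble::tibble(seqid = "c", seq = paste0(strrep("T", 50), flank, el,
                                                flank, strrep("T", 50)))
  cand <- tibble::tibble(element_id = "e", seqid = "c",
                         start = 59L, end = 58L + nchar(el))
  out <- detect_tsd(cand, g)
  expect_equal(out$tsd, "ACGTACGT")
  # a 2 bp duplication only
  g2 <- tibble::tibble(seqid = "c", seq = paste0(strrep("T", 50), "GGGGGGTA", el,
                                                 "TACCCCCC", strrep("T", 50)))
  out2 <- detect_tsd(cand, g2)
  expect_equal(out2$tsd, "TA")
  # no duplication at all (left flank all G, right flank all C)
  g3 <- tibble::tibble(seqid = "c", seq = paste0(strrep("G", 58), el,
                                                 strrep("C", 58)))
  out3 <- detect_tsd(cand, g3)
  expect_true(is.na(out3$tsd))
  # flank shorter than the longest allowed TSD -> skipped with warning
  g4 <- tibble::tibble(seqid = "c", seq = paste0("TATT", el, strrep("C", 50)))
  cand4 <- tibble::tibble(element_id = "e", seqid = "c",
                          start = 5L, end = 4L + nchar(el))
  expect_warning(out4 <- detect_tsd(cand4, g4), "too close")
  expect_true(is.na(out4$tsd))
})

test_that("AT content is strand-symmetric and rejects all-ambiguous input", {
  set.seed(67)
  for (i in 1:10) {
    s <- random_dna(50, gc = runif(1))
    expect_equal(at_content(s), at_content(revcomp(s)))
  }
  expect_error(at_content("NNNN"), "undefined|unambiguous")
  expect_equal(at_content("ANTN"), 1.0)  # ambiguity excluded from both sides
})

test_that("clustering separates families and is permutation-invariant", {
  cfg <- mite_config()
  set.seed(68)
  fam_a <- random_dna(300, gc = 0.3)
  fam_b <- random_dna(300, gc = 0.55)   # unrelated second family
  cands <- tibble::tibble(
    element_id = sprintf("e%d", 1:9),
    seqid = "c", start = 1L + 400L * (0:8), end = 300L + 400L * (0:8),
    length = 300L, tir_len = 12L, tir_identity = 1,
    tsd = c(rep("ACGTACGT", 4), rep("TA", 4), NA),
    tsd_len = c(rep(8L, 4), rep(2L, 4), NA),
    seq = c(vapply(1:4, function(i) evolve(fam_a, 0.04), ""),
            vapply(1:4, function(i) evolve(fam_b, 0.04), ""),
            random_dna(300)),
    at_fraction = 0.5, at_rich = FALSE)
  fams <- cluster_families(cands, cfg)
  expect_equal(nrow(fams$families), 2L)
  expect_equal(sort(fams$families$n_members), c(4L, 4L))
  expect_equal(fams$families$superfamily[fams$families$tsd_len_mode == 8],
               "hAT")
  expect_equal(fams$families$superfamily[fams$families$tsd_mode == "TA"],
               "Tc1/mariner")
  # the singleton stays outside any reported family
  singleton_fam <- fams$members$family_id[fams$members$element_id == "e9"]
  expect_false(singleton_fam %in% fams$families$family_id)
  # permutation of the input changes ids at most, not the partition
  perm <- sample(nrow(cands))
  fams2 <- cluster_families(cands[perm, ], cfg)
  part <- function(f) unname(split(f$members$element_id, f$members$family_id))
  expect_setequal(lapply(part(fams), sort), lapply(part(fams2), sort))
})

test_that("a singleton family's consensus equals its sequence", {
  cfg1 <- mite_config(min_family_size = 1L)
  set.seed(69)
  s <- random_dna(250, gc = 0.3)
  cands <- tibble::tibble(element_id = "only", seqid = "c", start = 1L,
                          end = 250L, length = 250L, tir_len = 12L,
                          tir_identity = 1, tsd = "ACGTACGT", tsd_len = 8L,
                          seq = s, at_fraction = 0.7, at_rich = TRUE)
  fams <- cluster_families(cands, cfg1)
  expect_equal(nrow(fams$families), 1L)
  expect_equal(fams$families$consensus, s)
})

test_that("superfamily rules follow the TSD diagnostics", {
  fam <- tibble::tibble(tsd_mode = c(NA, "ACGTACGT", "TA", "TAACCGGTT"),
                        tsd_len_mode = c(NA, 8L, 2L, 9L))
  expect_equal(classify_superfamily(fam),
               c("unknown", "hAT", "Tc1/mariner", "Mutator"))
})
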