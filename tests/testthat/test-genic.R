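toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    seqid = "chr1",
    start = c(10000L, 30000L),
    end = c(14000L, 33000L),
    strand = c("+", "-"),
    exons = list(tibble::tibble(start = c(10000L, 12000L),
                                end = c(10500L, 14000L)),
                 tibble::tibble(start = 30000L, end = 33000L)))
}

el <- function(id, start, end) {
  tibble::tibble(element_id = id, seqid = "chr1", start = start, end = end)
}

test_that("nearest gene distances are signed by transcription direction", {
  genes <- toy_genes()
  # inside a gene
  expect_equal(nearest_gene(el("in", 12500L, 12800L), genes)$distance, 0L)
  # ends 500 bp before a +-strand gene's start: 5' side, negative
  ng <- nearest_gene(el("up", 9000L, 9500L), genes)
  expect_equal(ng$nearest_gene_id, "gA")
  expect_equal(ng$signed_distance, -500L)
  # 5' of a minus-strand gene means to its right
  ng2 <- nearest_gene(el("upB", 33200L, 33400L), genes)
  expect_equal(ng2$signed_distance, -200L)
  # equidistant between gA end and gB start: lexicographically smaller wins
  mid <- el("tie", 22000L, 22001L)
  g_tie <- toy_genes()
  g_tie$end[1] <- 20000L
  g_tie$start[2] <- 24001L
  expect_equal(nearest_gene(mid, g_tie)$nearest_gene_id, "gA")
  # no genes on the seqid
  none <- nearest_gene(tibble::tibble(element_id = "x", seqid = "chrZ",
                                      start = 1L, end = 10L), genes)
  expect_true(is.na(none$distance))
})

test_that("position categories follow the exon > intron > flank precedence", {
  genes <- toy_genes()
  cfg <- mite_config()
  calls <- classify_position(dplyr::bind_rows(
    el("exonic", 10100L, 10300L),
    el("intronic", 10800L, 11500L),
    el("upstream", 9000L, 9500L),
    el("downstream", 14100L, 14600L),
    el("far", 20000L, 20500L),
    el("upB", 33500L, 34000L)), genes, cfg)
  expect_equal(calls$category,
               c("exon", "intron", "upstream", "downstream",
                 "intergenic", "upstream"))
  expect_true(all(table(calls$element_id) == 1L))  # categories partition
  # distance bound: 2,500 bp away with a 2,000 bp window is intergenic
  far <- classify_position(el("f", 16501L, 16600L), genes, cfg)
  expect_equal(far$category, "intergenic")
  near <- classify_position(el("n", 15999L, 16100L), genes, cfg)
  expect_equal(near$category, "downstream")
})

test_that("position calls are invariant under mirroring the landscape", {
  cfg <- mite_config()
  genes <- toy_genes()
  elements <- dplyr::bind_rows(
    el("a", 9200L, 9400L), el("b", 10100L, 10300L),
    el("c", 20000L, 20400L), el("d", 31000L, 31500L))
  L <- 50000L
  flip_iv <- function(s, e) list(start = L - e + 1L, end = L - s + 1L)
  m_el <- elements
  for (i in seq_len(nrow(m_el))) {
    f <- flip_iv(elements$start[i], elements$end[i])
    m_el$start[i] <- f$start; m_el$end[i] <- f$end
  }
  m_gn <- genes
  for (i in seq_len(nrow(m_gn))) {
    f <- flip_iv(genes$start[i], genes$end[i])
    m_gn$start[i] <- f$start; m_gn$end[i] <- f$end
    m_gn$strand[i] <- if (genes$strand[i] == "+") "-" else "+"
    ex <- genes$exons[[i]]
    fe <- flip_iv(ex$start, ex$end)
    m_gn$exons[[i]] <- tibble::tibble(start = rev(fe$start), end = rev(fe$end))
  }
  c1 <- classify_position(elements, genes, cfg)
  c2 <- classify_position(m_el, m_gn, cfg)
  expect_equal(c1$category, c2$category)
  expect_equal(c1$distance, c2$distance)
})

test_that("proximal fractions reproduce count/total percentages", {
  expect_equal(proximal_fraction(156, 331)$percent, 47)
  expect_equal(proximal_fraction(184, 434)$percent, 42)
  expect_equal(proximal_fraction(0, 100)$percent, 0)
  expect_equal(proximal_fraction(53, 53)$percent, 100)
  expect_error(proximal_fraction(5, 0), "total")
  expect_error(proximal_fraction(10, 5), "exceeds")
  calls <- classify_position(el("x", 9200L, 9400L), toy_genes(), mite_config())
  pf <- proximal_fraction(calls)
  expect_equal(pf$n_total, 1L)
  expect_equal(pf$percent, 100)
})

test_that("TSS/TTS profiles bin midpoint distances strand-aware", {
  genes <- toy_genes()
  # one element 250 bp upstream of gA's TSS (midpoint at -250)
  e <- el("u", 9700L, 9800L)
  prof <- tss_tts_profile(e, genes, window = 5000L, bin = 500L)
  tss <- prof[prof$site == "TSS", ]
  expect_equal(sum(tss$count), 1L)
  expect_equal(tss$count[tss$bin_start == -500L], 1L)
  # empty element set gives an all-zero histogram
  prof0 <- tss_tts_profile(e[0, ], genes, window = 5000L, bin = 500L)
  expect_true(all(prof0$count == 0L))
  # histogram total never exceeds the number of elements
  s <- small_sim()
  profS <- tss_tts_profile(s$sim$truth, s$sim$genes, config = s$cfg, bin = 500L)
  expect_lte(sum(profS$count[profS$site == "TSS"]), nrow(s$sim$truth))
  expect_error(tss_tts_profile(e, genes, window = 5000L, bin = 0L), "bin")
  expect_error(tss_tts_profile(e, genes, window = 5000L, bin = 999L), "divide")
})
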