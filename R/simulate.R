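# Synthetic study system: genomes with annotated genes, planted MITE
# families of known geometry and age, uniform-coverage reads, and truth
# tables, so every pipeline stage can be scored against ground truth.
#
# Elements evolve from their family consensus under a substitution-only
# Kimura two-parameter process (transition/transversion rate ratio 2:1),
# the same model class the dating machinery inverts; indel decay is
# deliberately not modelled so TIR/TSD structure survives by
# construction at age zero.

#' Simulate a background genome with gene annotations
#'
#' I.i.d. background sequence at the requested GC content with
#' non-overlapping genes (1-5 exons each) placed uniformly.
#'
#' @param length Genome length in bp (>= 10 kb).
#' @param gc GC fraction of the background.
#' @param n_genes Number of genes to place.
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @param seqid Sequence name.
#' @return A list of class `mite_sim` with `genome` (tibble `seqid`,
#'   `seq`, `length`), `genes` (see [read_genes_gff3()]) and an empty
#'   `truth` table.
#' @export
simulate_genome <- function(length, gc = 0.5, n_genes = 0L, seed = NULL,
                            seqid = "chr1") {
  stopifnot(length >= 10000L, n_genes >= 0L)
  if (!is.null(seed)) set.seed(seed)
  seq <- random_dna(length, gc)
  genes <- tibble(gene_id = character(), seqid = character(),
                  start = integer(), end = integer(), strand = character(),
                  exons = list())
  if (n_genes > 0L) {
    placed <- IRanges::IRanges()
    rows <- list()
    for (i in seq_len(n_genes)) {
      glen <- sample(1000:4000, 1L)
      ok <- FALSE
      for (try in seq_len(200L)) {
        s <- sample.int(length - glen, 1L)
        ir <- IRanges::IRanges(s, s + glen - 1L)
        if (length(placed) == 0L || IRanges::countOverlaps(ir, placed) == 0L) {
          placed <- c(placed, ir)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place ", n_genes, " non-overlapping genes; placed ", i - 1L)
      n_ex <- sample(1:5, 1L)
      # exon starts/ends: cut the span into 2*n_ex-1 alternating blocks
      cuts <- sort(sample(seq_len(glen - 1L), 2L * n_ex - 2L))
      bounds <- c(0L, cuts, glen)
      ex_start <- s + bounds[seq(1L, 2L * n_ex - 1L, by = 2L)]
      ex_end <- s + bounds[seq(2L, 2L * n_ex, by = 2L)] - 1L
      ex_start[1] <- s
      ex_end[n_ex] <- s + glen - 1L
      rows[[i]] <- tibble(
        gene_id = sprintf("gene%03d", i), seqid = seqid,
        start = s, end = s + glen - 1L,
        strand = sample(c("+", "-"), 1L),
        exons = list(tibble(start = as.integer(ex_start),
                            end = as.integer(ex_end))))
    }
    genes <- bind_rows(rows)
    genes <- genes[order(genes$start), ]
  }
  structure(list(
    genome = tibble(seqid = seqid, seq = seq, length = length),
    genes = genes,
    truth = empty_truth_tbl()
  ), class = "mite_sim")
}

empty_truth_tbl <- function() {
  tibble(element_id = character(), family_id = character(),
         seqid = character(), start = integer(), end = integer(),
         strand = character(), true_T = double(), true_k = double(),
         tsd = character(), seq = character())
}

#' Specification of a MITE family to plant
#'
#' Defaults mirror a compact hAT-like family: ~670 bp, an 8 bp TSD,
#' AT-rich, with an age mixture concentrated on a 2-3 Myr-old
#' amplification burst plus a minor older component.
#'
#' @param family_id Family label recorded in the truth table.
#' @param consensus Ancestral element sequence; `NULL` generates one of
#'   `length` bp at `at_fraction` AT whose last `tir_len` bases are the
#'   reverse complement of its first `tir_len` bases.
#' @param length,at_fraction Geometry of a generated consensus.
#' @param tir_len TIR length (>= 10 bp).
#' @param tsd_len TSD length (2-10 bp).
#' @param n_copies Copies to plant.
#' @param ages Tibble with `T_years` and `weight` (summing to 1): the
#'   discrete age mixture copies are drawn from.
#' @param genic_bias Fraction of copies targeted to within ~1 kb of a
#'   gene (the remainder insert uniformly).
#' @return A list of class `mite_plant_spec`.
#' @export
mite_plant_spec <- function(family_id, consensus = NULL, length = 670L,
                            at_fraction = 0.70, tir_len = 25L, tsd_len = 8L,
                            n_copies = 50L,
                            ages = tibble(T_years = c(1e6, 2e6, 2.5e6, 3e6),
                                          weight = c(0.2, 0.3, 0.3, 0.2)),
                            genic_bias = 0) {
  stopifnot(tir_len >= 10L, tsd_len >= 2L, tsd_len <= 10L,
            abs(sum(ages$weight) - 1) < 1e-8, n_copies >= 1L,
            genic_bias >= 0, genic_bias <= 1)
  if (is.null(consensus)) {
    core <- random_dna(length, gc = 1 - at_fraction)
    consensus <- paste0(substr(core, 1L, length - tir_len),
                        revcomp(substr(core, 1L, tir_len)))
    # pin the TIR to its designed length: every potential extension
    # endpoint out to the scanner's default 40 bp cap is forced to
    # mispair, so an undiverged copy reports exactly tir_len
    cv <- strsplit(consensus, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (t in (tir_len + 1L):min(40L, floor(length / 2))) {
      partner <- comp[[cv[length - t + 1L]]]
      if (cv[t] == partner) {
        cv[t] <- setdiff(c("A", "C", "G", "T"), partner)[sample.int(3L, 1L)]
      }
    }
    consensus <- paste(cv, collapse = "")
  }
  stopifnot(nchar(consensus) >= 2L * tir_len,
            substr(consensus, nchar(consensus) - tir_len + 1L, nchar(consensus)) ==
              revcomp(substr(consensus, 1L, tir_len)))
  structure(list(family_id = family_id, consensus = consensus,
                 tir_len = as.integer(tir_len), tsd_len = as.integer(tsd_len),
                 n_copies = as.integer(n_copies), ages = ages,
                 genic_bias = genic_bias),
            class = "mite_plant_spec")
}

# Evolve a sequence under K2P with transition/transversion rate ratio
# 2:1, scaled to an expected k substitutions per site.  Uses the exact
# finite-time substitution probabilities so the multiple-hit correction
# in the estimator is exercised honestly.
evolve_seq <- function(seq, k) {
  if (k <= 0) return(seq)
  codes <- encode_dna(seq)
  n <- length(codes)
  p_ts <- 0.25 + 0.25 * exp(-k) - 0.5 * exp(-1.5 * k)
  p_tv_each <- 0.25 - 0.25 * exp(-k)
  u <- runif(n)
  # transition partner: A<->G (1<->3), C<->T (2<->4)
  ts_target <- c(3L, 4L, 1L, 2L)
  # transversion partners for A,C,G,T
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  out <- codes
  sel <- !is.na(codes)
  take_ts <- sel & u < p_ts
  take_tv1 <- sel & u >= p_ts & u < p_ts + p_tv_each
  take_tv2 <- sel & u >= p_ts + p_tv_each & u < p_ts + 2 * p_tv_each
  out[take_ts] <- ts_target[codes[take_ts]]
  out[take_tv1] <- tv1[codes[take_tv1]]
  out[take_tv2] <- tv2[codes[take_tv2]]
  decode_dna(out, gap_as = "N")
}

#' Plant MITE copies into a simulated genome
#'
#' Per copy: an age `T` is drawn from the family's age mixture, the
#' expected divergence is set by the clock inverse `k = 2 r T`, the
#' consensus (and, independently, each copy of the target-site
#' duplication) is evolved under the K2P process, and the element is
#' inserted with the `tsd_len` bp target sequence duplicated on both
#' sides.  Gene coordinates are remapped across insertions, so an
#' insertion inside a gene lengthens it (and can land in an exon).
#'
#' Insertion points keep >= 400 bp from sequence ends and >= 800 bp from
#' each other, which guarantees clean polymorphism-locus flanks and keeps
#' gene-biased copies within the genic window even when another copy
#' lands in between.
#'
#' @param sim A `mite_sim` from [simulate_genome()] (or a prior
#'   [plant_mites()] call, to plant several families).
#' @param spec A [mite_plant_spec()] or list of them.
#' @param config A [mite_config()]; supplies the clock rate.
#' @param seed Integer seed.
#' @return The updated `mite_sim`: mutated genome, remapped genes, truth
#'   rows appended (`element_id`, `family_id`, interval, `true_T`,
#'   `true_k`, `tsd`, `seq`).
#' @export
plant_mites <- function(sim, spec, config = mite_config(), seed = NULL) {
  stopifnot(inherits(sim, "mite_sim"))
  if (inherits(spec, "mite_plant_spec")) spec <- list(spec)
  if (!is.null(seed)) set.seed(seed)
  r <- config$substitution_rate_r
  margin <- 400L
  min_gap <- 800L
  for (sp in spec) {
    gseq <- sim$genome$seq[[1]]
    seqid <- sim$genome$seqid[[1]]
    glen <- nchar(gseq)
    genes <- sim$genes
    # draw each copy's age and evolve it first: the insertion point must
    # then avoid flanking bases that would extend the TSD ambiguously
    # (base left of the target equal to the element's last base, or base
    # right of it equal to the element's first base)
    T_draw <- sample(sp$ages$T_years, sp$n_copies, replace = TRUE,
                     prob = sp$ages$weight)
    k_draw <- 2 * r * T_draw
    els <- vapply(k_draw, function(k) evolve_seq(sp$consensus, k), "")
    taken <- c(sim$truth$start, sim$truth$end)  # crude guard near old sites
    pos <- integer(0)
    for (i in seq_len(sp$n_copies)) {
      el_first <- substr(els[i], 1L, 1L)
      el_last <- substr(els[i], nchar(els[i]), nchar(els[i]))
      ok <- FALSE
      for (try in seq_len(1000L)) {
        if (runif(1) < sp$genic_bias && nrow(genes) > 0L) {
          g <- genes[sample.int(nrow(genes), 1L), ]
          lo <- max(margin, g$start - 1000L - nchar(sp$consensus))
          hi <- min(glen - margin, g$end + 1000L)
          if (hi <= lo) next
          p <- sample(lo:hi, 1L)
        } else {
          p <- sample((margin):(glen - margin), 1L)
        }
        if (p <= sp$tsd_len) next
        if (substr(gseq, p - sp$tsd_len, p - sp$tsd_len) == el_last) next
        if (substr(gseq, p + 1L, p + 1L) == el_first) next
        if (all(abs(p - pos) >= min_gap) &&
            (length(taken) == 0L || min(abs(p - taken)) >= min_gap)) {
          pos <- c(pos, p)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place copy ", i, " of ", sp$n_copies,
             " for ", sp$family_id, "; placed ", i - 1L)
      }
    }
    ord <- order(pos)
    pos <- pos[ord]
    T_draw <- T_draw[ord]
    k_draw <- k_draw[ord]
    els <- els[ord]
    # assemble the new sequence left to right
    pieces <- character(0)
    truth_rows <- list()
    prev <- 1L
    offset <- 0L
    for (i in seq_along(pos)) {
      p <- pos[i]
      target <- substr(gseq, p - sp$tsd_len + 1L, p)
      el <- els[i]
      left_tsd <- evolve_seq(target, k_draw[i])
      right_tsd <- evolve_seq(target, k_draw[i])
      pieces <- c(pieces, substr(gseq, prev, p - sp$tsd_len), left_tsd,
                  el, right_tsd)
      prev <- p + 1L
      new_start <- p + offset + 1L
      new_end <- new_start + nchar(el) - 1L
      truth_rows[[i]] <- tibble(
        element_id = sprintf("%s_%03d", sp$family_id, i),
        family_id = sp$family_id, seqid = seqid,
        start = new_start, end = new_end, strand = "+",
        true_T = T_draw[i], true_k = k_draw[i],
        tsd = target, seq = el)
      offset <- offset + nchar(el) + sp$tsd_len
    }
    pieces <- c(pieces, substr(gseq, prev, glen))
    new_seq <- paste(pieces, collapse = "")
    # remap prior truth and genes: positions strictly right of an
    # insertion point shift by element + TSD length
    ins_len <- nchar(sp$consensus) + sp$tsd_len
    shift <- function(x) as.integer(x + ins_len * vapply(x, function(xx) sum(pos < xx), 0))
    if (nrow(sim$truth) > 0L) {
      sim$truth$start <- shift(sim$truth$start)
      sim$truth$end <- shift(sim$truth$end)
    }
    if (nrow(genes) > 0L) {
      genes$start <- shift(genes$start)
      genes$end <- shift(genes$end)
      genes$exons <- lapply(genes$exons, function(ex) {
        tibble(start = shift(ex$start), end = shift(ex$end))
      })
      sim$genes <- genes
    }
    sim$genome$seq[[1]] <- new_seq
    sim$genome$length <- nchar(new_seq)
    sim$truth <- bind_rows(sim$truth, bind_rows(truth_rows))
  }
  sim$truth <- sim$truth[order(sim$truth$start), ]
  sim
}

#' Excise planted elements, restoring the empty allele
#'
#' Removes the element plus one flanking copy of its target site
#' duplication, i.e. the pre-insertion state.  The current genome content
#' at each interval must match the truth record's sequence, so excising
#' twice (or with stale coordinates) is an error.
#'
#' @param genome Genome tibble.
#' @param truth One or more truth rows from [plant_mites()].
#' @return The genome tibble with the element(s) removed.
#' @export
excise <- function(genome, truth) {
  check_genome(genome)
  truth <- truth[order(-truth$start), ]
  for (i in seq_len(nrow(truth))) {
    x <- truth[i, ]
    gseq <- genome_seq(genome, x$seqid)
    if (substr(gseq, x$start, x$end) != x$seq) {
      stop("genome content at ", x$seqid, ":", x$start, "-", x$end,
           " does not match the truth record (already excised?)")
    }
    tsd_len <- nchar(x$tsd)
    gi <- match(x$seqid, genome$seqid)
    genome$seq[[gi]] <- paste0(substr(gseq, 1L, x$start - 1L),
                               substr(gseq, x$end + tsd_len + 1L, nchar(gseq)))
    genome$length[gi] <- nchar(genome$seq[[gi]])
  }
  genome
}

#' Simulate uniform-coverage single-end reads
#'
#' Uniform start positions on both strands; per-base substitution errors
#' at `error_rate`; total bases approximately `coverage` times the genome
#' length.
#'
#' @param genome Genome tibble.
#' @param coverage Fold coverage (> 0).
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Reads tibble: `read_id`, `seq`, `seqid`, `start`, `strand`.
#' @export
simulate_reads <- function(genome, coverage, read_len = 100L,
                           error_rate = 0, seed = NULL) {
  check_genome(genome)
  stopifnot(coverage > 0, all(nchar(genome$seq) >= read_len))
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map(seq_len(nrow(genome)), function(gi) {
    gseq <- genome$seq[[gi]]
    glen <- nchar(gseq)
    n_reads <- round(coverage * glen / read_len)
    starts <- sample.int(glen - read_len + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(gseq, starts, starts + read_len - 1L)
    flip <- strands == "-"
    seqs[flip] <- revcomp(seqs[flip])
    if (error_rate > 0) {
      seqs <- vapply(seqs, add_read_errors, "", error_rate = error_rate,
                     USE.NAMES = FALSE)
    }
    tibble(read_id = sprintf("%s_r%06d", genome$seqid[[gi]], seq_len(n_reads)),
           seq = seqs, seqid = genome$seqid[[gi]], start = starts,
           strand = strands)
  })
  bind_rows(out)
}

add_read_errors <- function(seq, error_rate) {
  codes <- encode_dna(seq)
  hit <- which(runif(length(codes)) < error_rate & !is.na(codes))
  if (length(hit) == 0L) return(seq)
  codes[hit] <- ((codes[hit] - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L
  decode_dna(codes, gap_as = "N")
}

#' Score predicted elements against a truth table
#'
#' A prediction matches a truth record at reciprocal overlap >=
#' `min_overlap` (intersection at least that fraction of *both*
#' intervals); matching is greedy by overlap width and one-to-one.
#'
#' @param predicted Tibble with `seqid`, `start`, `end` (e.g.
#'   `tidy(discover_mites(...))`).
#' @param truth Truth table from [plant_mites()].
#' @param min_overlap Reciprocal overlap threshold.
#' @return One-row tibble: `n_truth`, `n_predicted`, `n_matched`,
#'   `precision`, `recall`, `precision_defined`.
#' @export
evaluate_discovery <- function(predicted, truth, min_overlap = 0.8) {
  if (nrow(predicted) == 0L) {
    return(tibble(n_truth = nrow(truth), n_predicted = 0L, n_matched = 0L,
                  precision = 0, recall = 0, precision_defined = FALSE))
  }
  pr <- GenomicRanges::GRanges(predicted$seqid,
                               IRanges::IRanges(predicted$start, predicted$end))
  tr <- GenomicRanges::GRanges(truth$seqid,
                               IRanges::IRanges(truth$start, truth$end))
  ov <- GenomicRanges::findOverlaps(pr, tr)
  w <- IRanges::width(IRanges::pintersect(pr[S4Vectors::queryHits(ov)],
                                          tr[S4Vectors::subjectHits(ov)]))
  ok <- w >= min_overlap * IRanges::width(pr[S4Vectors::queryHits(ov)]) &
    w >= min_overlap * IRanges::width(tr[S4Vectors::subjectHits(ov)])
  ov <- ov[ok]
  w <- w[ok]
  ord <- order(-w)
  used_p <- logical(nrow(predicted))
  used_t <- logical(nrow(truth))
  n_matched <- 0L
  for (i in ord) {
    p <- S4Vectors::queryHits(ov)[i]
    t <- S4Vectors::subjectHits(ov)[i]
    if (!used_p[p] && !used_t[t]) {
      used_p[p] <- TRUE
      used_t[t] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  tibble(n_truth = nrow(truth), n_predicted = nrow(predicted),
         n_matched = n_matched,
         precision = n_matched / nrow(predicted),
         recall = if (nrow(truth) > 0L) n_matched / nrow(truth) else NA_real_,
         precision_defined = TRUE)
}
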