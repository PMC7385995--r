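# Copy-number estimation.  Two independent estimators: intact-copy
# counting in an assembly (hits of the family consensus at >= 80 %
# identity over >= 80 % of the consensus, both strands, non-overlapping)
# and a read-depth estimate (mean depth of reads mapped to the consensus
# at > 80 % identity over > 50 % of the read, normalized to haploid
# genome coverage).  On a well-assembled genome the two agree; their
# divergence flags collapsed repeats.

#' Find intact copies of a consensus in an assembly
#'
#' @param consensus Family consensus sequence (>= 50 bp).
#' @param genome Genome tibble (`seqid`, `seq`).
#' @param config A [mite_config()]; supplies the identity/coverage
#'   thresholds (inclusive) and the seed length.
#' @param scoring An [align_scoring()] object.
#' @return A tibble of non-overlapping hits (`seqid`, `start`, `end`,
#'   `strand`, `score`, `identity`, `coverage_query`), sorted by
#'   position.  `nrow()` of the result is the intact-copy count.
#' @export
find_intact_copies <- function(consensus, genome, config = mite_config(),
                               scoring = align_scoring()) {
  stopifnot(nchar(consensus) >= 50L)
  check_genome(genome)
  out <- purrr::map(seq_len(nrow(genome)), function(i) {
    hits <- seeded_local_align(consensus, genome$seq[[i]],
                               seed_len = config$seed_len_assembly,
                               scoring = scoring, both_strands = TRUE)
    hits <- hits[hits$identity >= config$intact_min_identity &
                   hits$coverage_query >= config$intact_min_coverage, ]
    if (nrow(hits) == 0L) return(NULL)
    hits$seqid <- genome$seqid[[i]]
    hits
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(seqid = character(), start = integer(), end = integer(),
                  strand = character(), score = double(), identity = double(),
                  coverage_query = double()))
  }
  out <- out[order(out$seqid, out$s_start), ]
  tibble(seqid = out$seqid, start = out$s_start, end = out$s_end,
         strand = out$strand, score = out$score, identity = out$identity,
         coverage_query = out$coverage_query)
}

#' Map reads to a consensus and build a depth profile
#'
#' Each read is aligned locally to the consensus on both strands (after a
#' shared-seed prefilter) and contributes depth over its aligned
#' consensus positions iff identity exceeds `read_min_identity` and the
#' aligned fraction of the read exceeds `read_min_coverage` (both strict
#' inequalities).  A read contributes only at its best-scoring hit.
#'
#' @param reads Reads tibble (`read_id`, `seq`), e.g. from
#'   [simulate_reads()] or [read_reads()].
#' @param consensus Consensus sequence.
#' @param config A [mite_config()].
#' @param scoring An [align_scoring()] object.
#' @return A `mite_depth` tibble (`pos`, `depth`) over the consensus,
#'   with attributes `n_reads`, `n_mapped`, `consensus_len`.
#' @export
map_reads <- function(reads, consensus, config = mite_config(),
                      scoring = align_scoring()) {
  stopifnot(nrow(reads) >= 1L)
  L <- nchar(consensus)
  seed <- config$seed_len_reads
  stopifnot(all(nchar(reads$seq) >= seed))
  km <- c(substring(consensus, 1:(L - seed + 1L), seed:L))
  km <- unique(c(km, revcomp(km)))
  km <- km[!grepl("[^ACGT]", km)]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(km))
  rs <- Biostrings::DNAStringSet(reads$seq)
  cand <- which(Biostrings::vcountPDict(pd, rs, collapse = 2) > 0L)
  depth <- integer(L)
  n_mapped <- 0L
  if (length(cand) > 0L) {
    sm <- scoring_matrix(scoring)
    cons <- Biostrings::DNAString(consensus)
    starts <- integer(0)
    ends <- integer(0)
    for (st in c("+", "-")) {
      pat <- rs[cand]
      if (st == "-") pat <- Biostrings::reverseComplement(pat)
      pa <- Biostrings::pairwiseAlignment(
        pat, cons, type = "local", substitutionMatrix = sm,
        gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
      nm <- Biostrings::nmatch(pa)
      nmm <- Biostrings::nmismatch(pa)
      ident <- ifelse(nm + nmm == 0L, 0, nm / (nm + nmm))
      alen <- Biostrings::width(Biostrings::pattern(pa))
      covg <- alen / Biostrings::width(rs[cand])
      sc <- Biostrings::score(pa)
      if (st == "+") {
        best <- tibble(score = sc, ident = ident, covg = covg,
                       s_start = Biostrings::start(Biostrings::subject(pa)),
                       s_end = Biostrings::end(Biostrings::subject(pa)))
      } else {
        swap <- sc > best$score
        best$score[swap] <- sc[swap]
        best$ident[swap] <- ident[swap]
        best$covg[swap] <- covg[swap]
        best$s_start[swap] <- Biostrings::start(Biostrings::subject(pa))[swap]
        best$s_end[swap] <- Biostrings::end(Biostrings::subject(pa))[swap]
      }
    }
    pass <- best$ident > config$read_min_identity &
      best$covg > config$read_min_coverage
    n_mapped <- sum(pass)
    if (n_mapped > 0L) {
      cov <- IRanges::coverage(IRanges::IRanges(best$s_start[pass],
                                                best$s_end[pass]),
                               width = L)
      depth <- as.integer(cov)
    }
  }
  out <- tibble(pos = seq_len(L), depth = depth)
  attr(out, "n_reads") <- nrow(reads)
  attr(out, "n_mapped") <- n_mapped
  attr(out, "consensus_len") <- L
  class(out) <- c("mite_depth", class(out))
  out
}

#' Haploid genome coverage
#'
#' Total sequenced bases divided by haploid genome size; the normalizer
#' that converts element read depth into copies per haploid genome.
#'
#' @param total_read_bases Total bases sequenced.
#' @param genome_size Haploid genome size in bases (> 0).
#' @return Fold coverage (warns when there are no read bases).
#' @examples
#' estimate_haploid_coverage(1e7, 1e6)
#' @export
estimate_haploid_coverage <- function(total_read_bases, genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  if (total_read_bases == 0) warning("no read bases: coverage is 0")
  total_read_bases / genome_size
}

#' Copy number from a depth profile
#'
#' Trimmed mean of per-position depth over the central 80 % of the
#' consensus (ends under-recruit reads) divided by haploid coverage.
#'
#' @param profile A `mite_depth` tibble from [map_reads()].
#' @param haploid_coverage Fold coverage from
#'   [estimate_haploid_coverage()] (> 0).
#' @param trim Fraction trimmed off each consensus end.
#' @return Estimated copies per haploid genome.
#' @export
copy_number_from_depth <- function(profile, haploid_coverage, trim = 0.10) {
  if (haploid_coverage <= 0) stop("haploid_coverage must be > 0")
  L <- nrow(profile)
  cut <- floor(L * trim)
  core <- profile$depth[(cut + 1L):(L - cut)]
  mean(core) / haploid_coverage
}

#' Cross-genome specificity of family copy numbers
#'
#' For each family, the fold difference between the genome with the most
#' intact copies and every other genome.  A zero denominator yields `NA`.
#' `fold_display` is the floor of the fold, matching the convention of
#' reporting e.g. an 18.4-fold excess as "18-fold".
#'
#' @param estimates Tibble with `family_id`, `genome_id`, `intact_count`.
#' @return `estimates` plus `max_genome`, `fold`, `fold_display`.
#' @export
genome_specificity <- function(estimates) {
  stopifnot(all(c("family_id", "genome_id", "intact_count") %in% names(estimates)))
  counts <- table(estimates$family_id)
  if (all(counts < 2L)) stop("need >= 2 genomes sharing a family_id")
  estimates |>
    group_by(.data$family_id) |>
    mutate(max_genome = .data$genome_id[which.max(.data$intact_count)],
           fold = ifelse(.data$intact_count > 0,
                         max(.data$intact_count) / .data$intact_count,
                         NA_real_),
           fold_display = floor(.data$fold)) |>
    ungroup()
}
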