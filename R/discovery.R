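# De novo MITE discovery.  The structural definition does the work: a
# candidate is a 100-1000 bp window whose ends form a terminal inverted
# repeat (>= 10 bp at >= 90 % Hamming identity), usually flanked by an
# exact 2-10 bp target site duplication.  Chance inverted repeats are
# abundant in any genome, so candidates only graduate to elements through
# family evidence: clustering into multi-member families and re-searching
# the genome with each family consensus.

#' Scan a genome for TIR-bounded candidate windows
#'
#' Exhaustively scans every window of length `min_element_len` to
#' `max_element_len` for a terminal inverted repeat of at least
#' `min_tir_len` bp at `tir_min_identity` Hamming identity (no indels in
#' the TIR; ambiguity codes never match).  TSDs are detected for every
#' raw window and overlapping candidates are resolved by preferring the
#' longest TSD, then the longest TIR, then the leftmost start: the TSD is
#' direct physical evidence of the insertion boundary, and anchoring on
#' it stops chance one-or-two-base TIR extensions from nudging element
#' boundaries off the true insertion site.
#'
#' @param genome Genome tibble (`seqid`, `seq`), e.g. from
#'   [read_genome()] or [simulate_genome()].
#' @param config A [mite_config()].
#' @return A candidate tibble: `element_id`, `seqid`, `start`, `end`
#'   (1-based inclusive), `length`, `tir_len`, `tir_identity`, `tsd`,
#'   `tsd_len`, `seq`, `at_fraction`, `at_rich`.
#' @export
find_tir_candidates <- function(genome, config = mite_config()) {
  check_genome(genome)
  out <- purrr::map(seq_len(nrow(genome)), function(i) {
    gseq <- genome$seq[[i]]
    raw <- tir_scan_cpp(gseq,
                        config$min_element_len, config$max_element_len,
                        config$min_tir_len, config$max_tir_len,
                        1 - config$tir_min_identity)
    if (nrow(raw) == 0L) return(NULL)
    raw$tsd <- tsd_at(gseq, raw$start, raw$end, config)
    raw$tsd_len <- ifelse(is.na(raw$tsd), 0L, nchar(raw$tsd))
    ord <- order(-raw$tsd_len, -raw$tir_len, raw$start, raw$end)
    raw <- raw[ord, ]
    keep <- greedy_nonoverlap(raw$start, raw$end)
    raw <- raw[keep, ]
    raw <- raw[order(raw$start), ]
    seqs <- substring(gseq, raw$start, raw$end)
    tibble(seqid = genome$seqid[[i]], start = raw$start, end = raw$end,
           length = raw$end - raw$start + 1L,
           tir_len = raw$tir_len,
           tir_identity = 1 - raw$tir_mismatch / raw$tir_len,
           tsd = raw$tsd,
           tsd_len = ifelse(is.na(raw$tsd), NA_integer_, nchar(raw$tsd)),
           seq = seqs)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(element_id = character(), seqid = character(),
                  start = integer(), end = integer(), length = integer(),
                  tir_len = integer(), tir_identity = double(),
                  tsd = character(), tsd_len = integer(),
                  seq = character(), at_fraction = double(),
                  at_rich = logical()))
  }
  out$at_fraction <- at_content(out$seq)
  out$at_rich <- out$at_fraction >= config$at_rich_threshold
  out$element_id <- sprintf("%s:%d-%d", out$seqid, out$start, out$end)
  out[, c("element_id", "seqid", "start", "end", "length", "tir_len",
          "tir_identity", "tsd", "tsd_len", "seq", "at_fraction", "at_rich")]
}

# Vectorized TSD lookup: longest exact flanking duplication in
# [lo, hi]; NA when none or when the flank is too short for length hi.
tsd_at <- function(gseq, start, end, config) {
  lo <- config$tsd_len_range[1]
  hi <- config$tsd_len_range[2]
  glen <- nchar(gseq)
  tsd <- rep(NA_character_, length(start))
  eligible <- start - 1L >= hi & glen - end >= hi
  todo <- which(eligible)
  for (L in hi:lo) {
    if (length(todo) == 0L) break
    left <- substring(gseq, start[todo] - L, start[todo] - 1L)
    right <- substring(gseq, end[todo] + 1L, end[todo] + L)
    hit <- left == right & !grepl("[^ACGT]", left)
    tsd[todo[hit]] <- left[hit]
    todo <- todo[!hit]
  }
  tsd
}

# Greedy interval selection in priority order (input already sorted).
greedy_nonoverlap <- function(start, end) {
  n <- length(start)
  keep <- logical(n)
  ks <- integer(0)
  ke <- integer(0)
  for (i in seq_len(n)) {
    if (!any(start[i] <= ke & end[i] >= ks)) {
      keep[i] <- TRUE
      ks <- c(ks, start[i])
      ke <- c(ke, end[i])
    }
  }
  keep
}

#' Detect target site duplications flanking candidates
#'
#' A TSD is the longest exact duplication, with length inside
#' `config$tsd_len_range`, sitting immediately left of the element start
#' and immediately right of the element end.  Duplications containing
#' ambiguity codes do not count.  Candidates too close to a sequence end
#' for the longest allowed TSD are left `NA` with a warning.
#'
#' @param candidates Candidate tibble from [find_tir_candidates()].
#' @param genome Genome tibble the candidates refer to.
#' @param config A [mite_config()].
#' @return `candidates` with `tsd` and `tsd_len` columns added.
#' @export
detect_tsd <- function(candidates, genome, config = mite_config()) {
  check_genome(genome)
  hi <- config$tsd_len_range[2]
  glen <- setNames(nchar(genome$seq), genome$seqid)
  tsd <- rep(NA_character_, nrow(candidates))
  for (sid in unique(candidates$seqid)) {
    ix <- which(candidates$seqid == sid)
    tsd[ix] <- tsd_at(genome_seq(genome, sid),
                      candidates$start[ix], candidates$end[ix], config)
  }
  n_skipped <- sum(candidates$start - 1L < hi |
                     glen[candidates$seqid] - candidates$end < hi)
  if (n_skipped > 0L) {
    warning(n_skipped, " candidate(s) too close to a sequence end for TSD detection")
  }
  candidates$tsd <- tsd
  candidates$tsd_len <- ifelse(is.na(tsd), NA_integer_, nchar(tsd))
  candidates
}

#' Cluster candidates into families
#'
#' Incremental exemplar clustering: candidates are visited longest first
#' and join the first existing family whose exemplar they match at
#' `intact_min_identity` identity over `intact_min_coverage` of the
#' shorter sequence (either strand); otherwise they found a new family.
#' Shared-k-mer screening makes the no-match case (chance inverted
#' repeats, which dominate raw candidate lists) nearly free.  Family ids
#' are assigned in decreasing family size, and each family >=
#' `min_family_size` gets a majority consensus from a progressive
#' alignment of its members.
#'
#' @param candidates Candidate tibble with `tsd` column (see
#'   [detect_tsd()]).
#' @param config A [mite_config()].
#' @param scoring An [align_scoring()] object.
#' @return A list of class `mite_families`: `members` (candidates plus
#'   `family_id` and `member_strand`), and `families` (one row per family
#'   of at least `min_family_size` members: `family_id`, `n_members`,
#'   `consensus`, `consensus_len`, `tsd_len_mode`, `tsd_mode`,
#'   `superfamily`, `at_fraction`).
#' @export
cluster_families <- function(candidates, config = mite_config(),
                             scoring = align_scoring()) {
  stopifnot(is.data.frame(candidates))
  if (!"tsd" %in% names(candidates)) candidates$tsd <- NA_character_
  n <- nrow(candidates)
  if (n == 0L) {
    return(structure(list(members = candidates,
                          families = empty_family_tbl()),
                     class = "mite_families"))
  }
  # canonical visiting order: longest first, then sequence, so clustering
  # is invariant to input permutation
  ord <- order(-candidates$length, candidates$seq)
  cand <- candidates[ord, ]
  k <- config$seed_len_assembly
  kmer_sets <- lapply(cand$seq, canonical_kmers, k = k)
  index <- new.env(parent = emptyenv())   # kmer -> exemplar cluster ids
  exemplar <- integer(0)                  # row index of each cluster exemplar
  assign_to <- integer(n)
  strand_of <- character(n)
  min_shared <- 20L
  max_tries <- 8L
  for (i in seq_len(n)) {
    hits <- unlist(mget(kmer_sets[[i]], envir = index, ifnotfound = list(NULL)),
                   use.names = FALSE)
    cl <- 0L
    st <- "+"
    if (length(hits) > 0L) {
      tab <- sort(table(hits), decreasing = TRUE)
      tab <- tab[tab >= min_shared]
      for (cj in as.integer(names(head(tab, max_tries)))) {
        m <- match_pair(cand$seq[[i]], cand$seq[[exemplar[cj]]], config, scoring)
        if (!is.null(m)) { cl <- cj; st <- m; break }
      }
    }
    if (cl == 0L) {
      exemplar <- c(exemplar, i)
      cl <- length(exemplar)
      for (km in kmer_sets[[i]]) {
        assign(km, c(index[[km]], cl), envir = index)
      }
      st <- "+"
    }
    assign_to[i] <- cl
    strand_of[i] <- st
  }
  sizes <- tabulate(assign_to, nbins = length(exemplar))
  rank <- rank(-sizes, ties.method = "first")
  cand$family_id <- sprintf("fam%02d", rank[assign_to])
  cand$member_strand <- strand_of
  members <- cand[order(match(cand$element_id, candidates$element_id)), ]
  fam_ids <- sprintf("fam%02d", sort(rank[sizes >= config$min_family_size]))
  families <- purrr::map(fam_ids, function(fid) {
    mem <- members[members$family_id == fid, ]
    # the consensus is built from full-length members: diverged copies are
    # often picked up at inward-shifted frames or as fragments, and letting
    # them vote would erode the consensus ends
    mode_len <- as.integer(names(sort(table(mem$length), decreasing = TRUE))[1])
    full <- mem[abs(mem$length - mode_len) <= pmax(10, 0.02 * mode_len), ]
    if (nrow(full) < 2L) full <- mem
    seqs <- ifelse(full$member_strand == "-", revcomp(full$seq), full$seq)
    names(seqs) <- full$element_id
    cons <- if (length(seqs) >= 2L) {
      # gap-majority rule: columns carried by a minority of members
      # (flanking sequence dragged in by imperfect boundaries) are dropped
      gsub("-", "", consensus_row(progressive_msa(seqs, scoring),
                                  count_gaps = TRUE), fixed = TRUE)
    } else seqs[[1]]
    # TSD statistics also come from full-length members only: inward-
    # shifted frames of diverged copies carry a shared pseudo-duplication
    # of element-interior sequence that would distort the mode
    tsds <- full$tsd[!is.na(full$tsd)]
    tsd_mode <- if (length(tsds) > 0L) names(sort(table(tsds), decreasing = TRUE))[1] else NA_character_
    len_mode <- if (length(tsds) > 0L) {
      as.integer(names(sort(table(nchar(tsds)), decreasing = TRUE))[1])
    } else NA_integer_
    tibble(family_id = fid, n_members = nrow(mem), consensus = cons,
           consensus_len = nchar(cons), tsd_len_mode = len_mode,
           tsd_mode = tsd_mode, at_fraction = at_content(cons))
  })
  families <- bind_rows(families)
  if (nrow(families) == 0L) families <- empty_family_tbl()
  families$superfamily <- classify_superfamily(families)
  structure(list(members = members, families = families),
            class = "mite_families")
}

empty_family_tbl <- function() {
  tibble(family_id = character(), n_members = integer(),
         consensus = character(), consensus_len = integer(),
         tsd_len_mode = integer(), tsd_mode = character(),
         at_fraction = double(), superfamily = character())
}

canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  km <- unique(substring(seq, 1:(n - k + 1L), k:n))
  km <- km[!grepl("[^ACGT]", km)]
  # drop low-complexity k-mers (<= 2 distinct bases): in AT-rich elements
  # they are shared between unrelated sequences and only cost alignments
  km <- km[!grepl("^[AT]+$|^[AC]+$|^[AG]+$|^[CT]+$|^[CG]+$|^[GT]+$", km)]
  unique(pmin(km, revcomp(km)))
}

# Do two candidate sequences belong to the same family?  The family edge
# is identity >= intact_min_identity over >= intact_min_coverage of the
# shorter sequence, either orientation.  Returns the orientation of `a`
# relative to `b` ("+"/"-") or NULL.
match_pair <- function(a, b, config, scoring) {
  if (nchar(a) <= nchar(b)) { q <- a; s <- b } else { q <- b; s <- a }
  sm <- scoring_matrix(scoring)
  subj <- Biostrings::DNAString(s)
  best <- NULL
  for (st in c("+", "-")) {
    qq <- if (st == "+") q else revcomp(q)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qq), subj, type = "local",
      substitutionMatrix = sm, gapOpening = -scoring$gap_open,
      gapExtension = -scoring$gap_extend)
    nm <- Biostrings::nmatch(pa)
    nmm <- Biostrings::nmismatch(pa)
    if (nm + nmm == 0L) next
    ident <- nm / (nm + nmm)
    covg <- Biostrings::width(Biostrings::pattern(pa)) / nchar(q)
    # family members differ by substitutions, not rearrangement: a
    # gap-heavy alignment (as low-complexity AT-rich junk produces)
    # is not family evidence
    gap_frac <- 1 - (nm + nmm) / Biostrings::nchar(pa)
    if (ident >= config$intact_min_identity &&
        covg >= config$intact_min_coverage &&
        gap_frac <= 0.05 &&
        (is.null(best) || Biostrings::score(pa) > best$score)) {
      best <- list(strand = st, score = Biostrings::score(pa))
    }
  }
  if (is.null(best)) NULL else best$strand
}

#' TSD-based superfamily classification
#'
#' Looks the modal TSD of each family up in a rule table keyed on TSD
#' motif or length.  The shipped default table encodes the conventional
#' diagnostics -- an 8 bp TSD marks the hAT superfamily, a "TA" TSD
#' Tc1/mariner, "TAA"/"TTA" PIF/Harbinger, 9-11 bp Mutator -- and can be
#' replaced wholesale via `rules`.  Families with no TSD-bearing member
#' are "unknown".
#'
#' @param families Family tibble with `tsd_mode` and `tsd_len_mode`
#'   columns (or a `mite_families` object).
#' @param rules A rule table as returned by [superfamily_rules()].
#' @return Character vector of superfamily labels.
#' @export
classify_superfamily <- function(families, rules = superfamily_rules()) {
  if (inherits(families, "mite_families")) families <- families$families
  vapply(seq_len(nrow(families)), function(i) {
    motif <- families$tsd_mode[i]
    len <- families$tsd_len_mode[i]
    if (is.na(len)) return("unknown")
    # the modal motif only speaks for the family when it has the modal
    # length; otherwise a couple of eroded-TSD members sharing a chance
    # short duplication could override the length diagnostic
    hit <- rules[rules$key == "motif" & rules$value == motif, ]
    if (!is.na(motif) && nchar(motif) == len && nrow(hit) > 0L) {
      return(hit$superfamily[1])
    }
    len_rules <- rules[rules$key == "length", ]
    hit <- len_rules[as.integer(len_rules$value) == len, ]
    if (nrow(hit) > 0L) return(hit$superfamily[1])
    "unknown"
  }, "")
}

#' @rdname classify_superfamily
#' @export
superfamily_rules <- function() {
  tibble(
    key = c("motif", "motif", "motif", "length", "length", "length", "length"),
    value = c("TA", "TAA", "TTA", "8", "9", "10", "11"),
    superfamily = c("Tc1/mariner", "PIF/Harbinger", "PIF/Harbinger",
                    "hAT", "Mutator", "Mutator", "Mutator")
  )
}

#' Run the full de novo discovery pipeline
#'
#' Chains the structural scan, TSD detection, family clustering and a
#' consensus-based homology sweep: each family consensus is searched back
#' against the genome (see [find_intact_copies()]) so that family members
#' too diverged for the strict structural scan are still recovered.  Hits
#' from different families competing for the same locus are resolved by
#' alignment score.
#'
#' @param genome Genome tibble (`seqid`, `seq`).
#' @param config A [mite_config()].
#' @param scoring An [align_scoring()] object.
#' @return A `mite_discovery` object: list with `candidates` (structural
#'   scan output), `families`, `elements` (final per-copy table) and
#'   `config`.  `tidy()` returns the element table, `glance()` a one-row
#'   summary.
#' @export
discover_mites <- function(genome, config = mite_config(),
                           scoring = align_scoring()) {
  check_genome(genome)
  candidates <- find_tir_candidates(genome, config)
  fams <- cluster_families(candidates, config, scoring)
  hits <- purrr::map(seq_len(nrow(fams$families)), function(i) {
    f <- fams$families[i, ]
    h <- find_intact_copies(f$consensus, genome, config, scoring)
    if (nrow(h) > 0L) h$family_id <- f$family_id
    h
  })
  hits <- bind_rows(hits)
  if (nrow(hits) > 0L) {
    # resolve cross-family competition for a locus by score
    hits <- hits[order(-hits$score, hits$seqid, hits$start), ]
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$seqid), function(ix) {
      ix[greedy_nonoverlap(hits$start[ix], hits$end[ix])]
    }), use.names = FALSE)
    hits <- hits[sort(keep), ]
    hits$element_id <- sprintf("%s:%d-%d", hits$seqid, hits$start, hits$end)
    hits$length <- hits$end - hits$start + 1L
    hits$seq <- vapply(seq_len(nrow(hits)), function(i) {
      substring(genome_seq(genome, hits$seqid[i]), hits$start[i], hits$end[i])
    }, "")
    hits$at_fraction <- at_content(hits$seq)
    hits <- detect_tsd(hits, genome, config)
    hits <- hits[, c("element_id", "seqid", "start", "end", "length",
                     "strand", "family_id", "score", "identity",
                     "coverage_query", "seq", "at_fraction", "tsd", "tsd_len")]
  } else {
    hits <- tibble(element_id = character(), seqid = character(),
                   start = integer(), end = integer(), length = integer(),
                   strand = character(), family_id = character(),
                   score = double(), identity = double(),
                   coverage_query = double(), seq = character(),
                   at_fraction = double(), tsd = character(),
                   tsd_len = integer())
  }
  structure(list(candidates = candidates, families = fams$families,
                 members = fams$members, elements = as_tibble(hits),
                 config = config),
            class = "mite_discovery")
}

#' @export
print.mite_discovery <- function(x, ...) {
  cat("<mite_discovery>\n")
  cat(sprintf("  structural candidates : %d\n", nrow(x$candidates)))
  cat(sprintf("  families (>= %d members): %d\n",
              x$config$min_family_size, nrow(x$families)))
  cat(sprintf("  elements (consensus hits): %d\n", nrow(x$elements)))
  if (nrow(x$families) > 0L) {
    print(x$families[, c("family_id", "n_members", "consensus_len",
                         "tsd_len_mode", "superfamily", "at_fraction")])
  }
  invisible(x)
}
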