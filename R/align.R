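# Pairwise alignment machinery shared by discovery, copy counting, read
# mapping and locus typing.  Dynamic programming is delegated to
# Biostrings::pairwiseAlignment(); this file owns seeding, windowing,
# coordinate bookkeeping and the identity/coverage definitions used by the
# intact-copy and read-mapping thresholds.

# Substitution matrix over the full DNA alphabet: only exact A/C/G/T
# matches score as matches, every pair involving an ambiguity code
# (including N-N) scores as a mismatch.
scoring_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
               "V", "H", "D", "B", "N")
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m)[1:4] <- scoring$match
  m[5:15, 5:15] <- scoring$mismatch
  m
}

# Identity over aligned columns where both rows carry a residue; ambiguity
# codes never match.  Returns NaN when there are no such columns.
aln_identity <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (n == 0L) return(NaN)
  good <- c("A", "C", "G", "T")
  sum(a[both] == b[both] & a[both] %in% good) / n
}

#' Global pairwise alignment
#'
#' Optimal end-to-end alignment under affine gap scoring.
#'
#' @param a,b Nucleotide strings (nonempty).
#' @param scoring An [align_scoring()] object.
#' @return A one-row tibble with `aligned_a`, `aligned_b`, `score`,
#'   `identity` (fraction of gap-free aligned columns with equal
#'   unambiguous residues) and `length` (alignment columns).
#' @examples
#' global_align("ACGT", "ACCT")$identity
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0L, nchar(b) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = scoring_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  qa <- as.character(Biostrings::alignedPattern(pa))
  sa <- as.character(Biostrings::alignedSubject(pa))
  tibble(aligned_a = unname(qa), aligned_b = unname(sa),
         score = Biostrings::score(pa),
         identity = aln_identity(qa, sa),
         length = nchar(qa))
}

#' Seed-and-extend local alignment
#'
#' BLAST-like search of a query in a (possibly much longer) subject:
#' exact-match seeds of length `seed_len` anchor candidate subject
#' windows, each window is locally aligned to the query, and overlapping
#' hits on the subject are merged keeping the best score.  The reverse
#' strand is searched by aligning against the reverse complement of the
#' subject; reported coordinates are always on the forward subject.
#'
#' @param query,subject Nucleotide strings.
#' @param seed_len Exact seed length (>= 8).
#' @param scoring An [align_scoring()] object.
#' @param both_strands Search the reverse strand too?
#' @param min_score Discard hits scoring below this.
#' @return A tibble sorted by descending score with columns `s_start`,
#'   `s_end`, `strand`, `q_start`, `q_end`, `score`, `identity`,
#'   `coverage_query` (aligned query fraction).
#' @export
seeded_local_align <- function(query, subject, seed_len = 12L,
                               scoring = align_scoring(),
                               both_strands = TRUE, min_score = 10) {
  stopifnot(seed_len >= 8L, nchar(query) >= seed_len, nchar(subject) >= 1L)
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- purrr::map(strands, function(st) {
    subj <- if (st == "+") subject else revcomp(subject)
    h <- local_hits_one_strand(query, subj, seed_len, scoring, min_score)
    if (nrow(h) == 0L) return(h)
    if (st == "-") {
      L <- nchar(subject)
      tmp <- h$s_start
      h$s_start <- L - h$s_end + 1L
      h$s_end <- L - tmp + 1L
    }
    h$strand <- st
    h
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble(s_start = integer(), s_end = integer(),
                  strand = character(), q_start = integer(),
                  q_end = integer(), score = double(), identity = double(),
                  coverage_query = double()))
  }
  hits <- hits[order(-hits$score, hits$s_start), ]
  keep <- merge_by_score(hits$s_start, hits$s_end)
  hits <- hits[keep, , drop = FALSE]
  as_tibble(hits[, c("s_start", "s_end", "strand", "q_start", "q_end",
                     "score", "identity", "coverage_query")])
}

# Greedy selection of mutually non-overlapping intervals; input must be
# ordered by priority (best first).
merge_by_score <- function(start, end) {
  n <- length(start)
  keep <- logical(n)
  if (n == 0L) return(keep)
  kept <- IRanges::IRanges()
  for (i in seq_len(n)) {
    ir <- IRanges::IRanges(start[i], end[i])
    if (length(kept) == 0L ||
        IRanges::countOverlaps(ir, kept) == 0L) {
      keep[i] <- TRUE
      kept <- c(kept, ir)
    }
  }
  keep
}

local_hits_one_strand <- function(query, subj, seed_len, scoring, min_score) {
  empty <- tibble(s_start = integer(), s_end = integer(),
                  q_start = integer(), q_end = integer(),
                  score = double(), identity = double(),
                  coverage_query = double())
  lq <- nchar(query)
  ls <- nchar(subj)
  if (ls < seed_len) return(empty)
  kmers <- substring(query, seq_len(lq - seed_len + 1L),
                     seq_len(lq - seed_len + 1L) + seed_len - 1L)
  clean <- !grepl("[^ACGT]", kmers)
  if (!any(clean)) return(empty)
  qpos <- which(clean)
  km <- kmers[clean]
  uk <- unique(km)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uk))
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
  spos_list <- IRanges::start(mi)
  nhit <- lengths(spos_list)
  if (sum(nhit) == 0L) return(empty)
  # implied full-query windows on the subject, one per seed hit
  idx <- rep(seq_along(uk), nhit)
  spos <- unlist(spos_list, use.names = FALSE)
  # a k-mer can occur at several query offsets
  qoff <- split(qpos, km)[uk]
  offs <- qoff[idx]
  sp_rep <- rep(spos, lengths(offs))
  off_flat <- unlist(offs, use.names = FALSE)
  wins <- IRanges::reduce(
    IRanges::IRanges(pmax(1L, sp_rep - (off_flat - 1L) - 20L),
                     pmin(ls, sp_rep + (lq - off_flat) + 20L)),
    min.gapwidth = 30L)
  sm <- scoring_matrix(scoring)
  qd <- Biostrings::DNAString(query)
  out <- purrr::map(seq_along(wins), function(w) {
    ws <- IRanges::start(wins)[w]
    we <- IRanges::end(wins)[w]
    pa <- Biostrings::pairwiseAlignment(
      qd, Biostrings::DNAString(substr(subj, ws, we)),
      type = "local", substitutionMatrix = sm,
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
    sc <- Biostrings::score(pa)
    if (sc < min_score) return(NULL)
    qa <- as.character(Biostrings::alignedPattern(pa))
    sa <- as.character(Biostrings::alignedSubject(pa))
    qs <- Biostrings::start(Biostrings::pattern(pa))
    qe <- Biostrings::end(Biostrings::pattern(pa))
    tibble(s_start = ws + Biostrings::start(Biostrings::subject(pa)) - 1L,
           s_end = ws + Biostrings::end(Biostrings::subject(pa)) - 1L,
           q_start = qs, q_end = qe,
           score = sc, identity = aln_identity(qa, sa),
           coverage_query = (qe - qs + 1L) / lq)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) empty else out
}
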