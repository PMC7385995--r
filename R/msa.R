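# Progressive multiple alignment and consensus calling.  Family members
# are near-full-length copies of a common ancestor, so a simple
# consensus-guided progressive scheme is adequate: sequences are added in
# decreasing k-mer similarity to the first sequence, each aligned globally
# against the running column consensus, with "once a gap, always a gap"
# column insertion.

#' Progressive multiple sequence alignment
#'
#' @param seqs Character vector (>= 2) of nucleotide strings, optionally
#'   named; unnamed input gets `seq1`, `seq2`, ... ids.
#' @param scoring An [align_scoring()] object.
#' @return An MSA tibble with columns `taxon` and `aligned` (equal-length
#'   gapped strings).  Ungapping row *i* reproduces input *i* exactly.
#' @examples
#' progressive_msa(c(a = "ACGTACGT", b = "ACGACGT"))
#' @export
progressive_msa <- function(seqs, scoring = align_scoring()) {
  if (length(seqs) < 2L) stop("progressive_msa() needs at least 2 sequences")
  stopifnot(all(nchar(seqs) > 0L))
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  if (is.null(names(seqs))) names(seqs) <- ids
  ord <- c(1L, 1L + order(kmer_similarity(seqs[1], seqs[-1]), decreasing = TRUE))
  rows <- matrix(strsplit(seqs[[ord[1]]], "")[[1]], nrow = 1)
  for (i in ord[-1]) {
    cons <- apply(rows, 2, majority_base)
    al <- global_align(paste(cons, collapse = ""), seqs[[i]], scoring)
    ac <- strsplit(al$aligned_a, "")[[1]]
    an <- strsplit(al$aligned_b, "")[[1]]
    new_rows <- matrix("-", nrow(rows) + 1L, length(ac))
    col <- 0L
    for (c_i in seq_along(ac)) {
      if (ac[c_i] == "-") {
        new_rows[nrow(new_rows), c_i] <- an[c_i]
      } else {
        col <- col + 1L
        new_rows[seq_len(nrow(rows)), c_i] <- rows[, col]
        new_rows[nrow(new_rows), c_i] <- an[c_i]
      }
    }
    rows <- new_rows
  }
  aligned <- apply(rows, 1, paste, collapse = "")
  tibble(taxon = ids[ord], aligned = aligned)[order(match(ids[ord], ids)), ]
}

# shared 8-mer counts against a reference sequence
kmer_similarity <- function(ref, others, k = 8L) {
  kset <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  rk <- kset(ref)
  vapply(others, function(s) length(intersect(kset(s), rk)), 1L)
}

# Majority base of a column; ties broken A < C < G < T; all-gap columns
# return "-".  With `count_gaps`, a column where gaps are the plurality
# is also "-": used for family consensus so that flanking sequence
# carried by a minority of members does not accrete onto the consensus.
majority_base <- function(chars, count_gaps = FALSE) {
  base_chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(base_chars) == 0L) return("-")
  counts <- table(factor(base_chars, levels = c("A", "C", "G", "T")))
  if (count_gaps && max(counts) < sum(!(chars %in% c("A", "C", "G", "T")))) {
    return("-")
  }
  names(counts)[which.max(counts)]
}

# Per-column consensus of selected MSA rows, in the alignment frame
# (length = number of columns; all-gap columns yield "-").
consensus_row <- function(msa, rows = seq_len(nrow(msa)), count_gaps = FALSE) {
  m <- do.call(rbind, strsplit(msa$aligned[rows], ""))
  paste(apply(m, 2, majority_base, count_gaps = count_gaps), collapse = "")
}

#' Majority consensus with balanced clade sampling
#'
#' Computes a per-column majority consensus over the alignment, optionally
#' down-sampling each clade to the same number of members first.  Balanced
#' sampling avoids biasing the consensus toward the most numerous
#' subfamily, which matters when the consensus is subsequently used as the
#' ancestral proxy for divergence dating.
#'
#' @param msa MSA tibble (`taxon`, `aligned`).
#' @param clades Named character vector mapping taxon -> clade label, or
#'   `NULL` to use all rows as one clade.
#' @param per_clade_n Members sampled per clade without replacement
#'   (clades smaller than this are used in full).
#' @param seed Integer seed for the sampling; `NULL` uses the current RNG
#'   state.
#' @return The ungapped consensus string (all-gap columns dropped), with
#'   attributes `in_frame` (consensus in alignment coordinates) and
#'   `sampled` (taxa used).
#' @export
balanced_consensus <- function(msa, clades = NULL, per_clade_n = Inf,
                               seed = NULL) {
  stopifnot(nrow(msa) >= 1L)
  if (is.null(clades)) clades <- setNames(rep("all", nrow(msa)), msa$taxon)
  if (length(clades) == 0L) stop("empty clade map")
  stopifnot(per_clade_n >= 1)
  missing <- setdiff(msa$taxon, names(clades))
  if (length(missing) > 0L) {
    stop("taxa without a clade assignment: ", paste(head(missing, 3), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  sampled <- unlist(lapply(split(msa$taxon, clades[msa$taxon]), function(members) {
    if (length(members) <= per_clade_n) members
    else sample(members, per_clade_n)
  }), use.names = FALSE)
  rows <- match(sampled, msa$taxon)
  in_frame <- consensus_row(msa, rows)
  out <- gsub("-", "", in_frame, fixed = TRUE)
  attr(out, "in_frame") <- in_frame
  attr(out, "sampled") <- sampled
  out
}
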