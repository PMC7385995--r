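#' Reverse complement of a nucleotide string
#'
#' Strict-base complementing; IUPAC ambiguity codes are complemented too
#' (e.g. R <-> Y), `N` stays `N`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' AT fraction of a sequence
#'
#' `(A + T) / (A + C + G + T)`: ambiguity codes are excluded from both the
#' numerator and the denominator.  MITEs are characteristically AT-rich
#' (around 70--75 % in well-described families), so this statistic is
#' carried on every candidate.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector of AT fractions in `[0, 1]`.
#' @examples
#' at_content(c("ATAT", "GCGC", "ATGC"))
#' @export
at_content <- function(seq) {
  stopifnot(is.character(seq), all(nchar(seq) > 0L))
  fr <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seq),
                                      baseOnly = TRUE)
  unamb <- rowSums(fr[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(unamb == 0)) {
    stop("at_content() is undefined for sequences with no unambiguous bases")
  }
  unname(rowSums(fr[, c("A", "T"), drop = FALSE]) / unamb)
}

#' Random DNA at a given GC content
#'
#' I.i.d. background sequence; A and T (and C and G) are equiprobable.
#'
#' @param n Length in bases.
#' @param gc GC fraction in `[0, 1]`.
#' @return A single nucleotide string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Integer encoding used by the K2P machinery: A=1, C=2, G=3, T=4, other=NA.
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  code <- rep(NA_integer_, 256L)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(x)]
}

# Rows of a character-matrix encoding for a set of equal-length strings.
encode_dna_matrix <- function(x) {
  stopifnot(is.character(x), length(unique(nchar(x))) == 1L)
  do.call(rbind, lapply(x, encode_dna))
}

decode_dna <- function(codes, gap_as = "-") {
  bases <- c("A", "C", "G", "T")
  out <- bases[codes]
  out[is.na(out)] <- gap_as
  paste(out, collapse = "")
}

check_genome <- function(genome) {
  stopifnot(is.data.frame(genome),
            all(c("seqid", "seq") %in% names(genome)),
            nrow(genome) >= 1L,
            !anyDuplicated(genome$seqid),
            all(nchar(genome$seq) >= 1L))
  invisible(genome)
}

genome_seq <- function(genome, seqid) {
  i <- match(seqid, genome$seqid)
  if (is.na(i)) stop("unknown seqid: ", seqid)
  genome$seq[[i]]
}
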