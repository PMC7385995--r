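# Kimura two-parameter divergence.  Sites with a gap or ambiguity code in
# either row are excluded (pairwise deletion); transitions (A<->G, C<->T)
# and transversions are corrected separately:
#   k = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)
# with P and Q the transition and transversion proportions per compared
# site.  Distances outside the formula's domain are "saturated".

# counts for one encoded pair of rows (codes 1..4, NA = excluded)
k2p_counts <- function(ca, cb) {
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  a <- ca[ok]
  b <- cb[ok]
  diff <- a != b
  ts <- sum(diff & (a %% 2L) == (b %% 2L))  # purines A,G odd; pyrimidines even
  list(n = n, ts = ts, tv = sum(diff) - ts)
}

k2p_from_PQ <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura two-parameter distance between two aligned rows
#'
#' @param row_a,row_b Equal-length gapped nucleotide strings.
#' @return A one-row tibble with `P` (transition proportion), `Q`
#'   (transversion proportion), `k` (substitutions per site) and
#'   `compared_sites`.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAT")
#' @export
k2p_distance <- function(row_a, row_b) {
  stopifnot(is.character(row_a), is.character(row_b),
            nchar(row_a) == nchar(row_b))
  cc <- k2p_counts(encode_dna(row_a), encode_dna(row_b))
  if (cc$n == 0L) stop("no comparable sites (all gapped or ambiguous)")
  P <- cc$ts / cc$n
  Q <- cc$tv / cc$n
  k <- k2p_from_PQ(P, Q)
  if (is.na(k)) {
    stop(sprintf("K2P distance saturated (P = %.3f, Q = %.3f)", P, Q))
  }
  tibble(P = P, Q = Q, k = k, compared_sites = cc$n)
}

# Vectorised all-pairs K2P over an encoded row matrix (rows = taxa).
# Each row is compared against all later rows with matrix arithmetic.
# Saturated or incomparable pairs become NA.
k2p_matrix_encoded <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  D <- matrix(0, n, n)
  valid <- !is.na(m)
  parity <- m %% 2L  # purines A,G are odd; pyrimidines C,T even
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    nj <- length(js)
    row_i <- matrix(m[i, ], nj, L, byrow = TRUE)
    ok <- valid[js, , drop = FALSE] &
      matrix(valid[i, ], nj, L, byrow = TRUE)
    diff <- ok & (m[js, , drop = FALSE] != row_i)
    same_par <- parity[js, , drop = FALSE] ==
      matrix(parity[i, ], nj, L, byrow = TRUE)
    ncomp <- rowSums(ok)
    ts <- rowSums(diff & same_par)
    tv <- rowSums(diff) - ts
    P <- ts / ncomp
    Q <- tv / ncomp
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    k <- ifelse(ncomp > 0L & w1 > 0 & w2 > 0,
                -0.5 * log(pmax(w1, 1e-300)) - 0.25 * log(pmax(w2, 1e-300)),
                NA_real_)
    D[i, js] <- k
    D[js, i] <- k
  }
  D
}

#' All-pairs K2P distance matrix for an alignment
#'
#' @param msa MSA tibble (`taxon`, `aligned`).
#' @return A symmetric numeric matrix with taxa as dimnames; saturated or
#'   incomparable pairs are `NA`.
#' @export
k2p_matrix <- function(msa) {
  m <- encode_dna_matrix(msa$aligned)
  D <- k2p_matrix_encoded(m)
  dimnames(D) <- list(msa$taxon, msa$taxon)
  D
}
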