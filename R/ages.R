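# Insertion-age dating.  A transposable element stops recruiting
# family-wide sequence once it inserts, so its divergence from the family
# consensus (a proxy for the ancestral sequence at the amplification
# burst) clocks its age: T = k / (2 r), with k the K2P substitutions per
# site and r the neutral per-site per-year substitution rate.

#' Per-element insertion-age estimates
#'
#' Computes K2P divergence of every alignment row to a consensus and
#' converts it to years with `T = k / (2 r)`.  Saturated rows are flagged
#' and get `NA` ages rather than aborting the batch.
#'
#' @param msa MSA tibble (`taxon`, `aligned`).
#' @param consensus Consensus in the alignment frame (same length as the
#'   alignment rows), e.g. from [balanced_consensus()]; `NULL` computes a
#'   plain majority consensus over all rows.
#' @param config A [mite_config()]; supplies `substitution_rate_r`.
#' @return A tibble with `element_id`, `P`, `Q`, `k`, `T_years`,
#'   `saturated`, of class `mite_ages`.
#' @export
element_ages <- function(msa, consensus = NULL, config = mite_config()) {
  stopifnot(nrow(msa) >= 1L)
  if (is.null(consensus)) {
    consensus <- consensus_row(msa)
  } else if (!is.null(attr(consensus, "in_frame"))) {
    consensus <- attr(consensus, "in_frame")
  }
  if (nchar(consensus) != nchar(msa$aligned[1])) {
    stop("consensus is not in the alignment frame ",
         "(use the `in_frame` attribute of balanced_consensus())")
  }
  cc <- encode_dna(consensus)
  r <- config$substitution_rate_r
  rows <- purrr::map(seq_len(nrow(msa)), function(i) {
    cnt <- k2p_counts(encode_dna(msa$aligned[i]), cc)
    if (cnt$n == 0L) {
      return(tibble(element_id = msa$taxon[i], P = NA_real_, Q = NA_real_,
                    k = NA_real_, T_years = NA_real_, saturated = TRUE))
    }
    P <- cnt$ts / cnt$n
    Q <- cnt$tv / cnt$n
    k <- k2p_from_PQ(P, Q)
    tibble(element_id = msa$taxon[i], P = P, Q = Q, k = k,
           T_years = k / (2 * r), saturated = is.na(k))
  })
  out <- bind_rows(rows)
  class(out) <- c("mite_ages", class(out))
  out
}

#' Histogram of insertion ages
#'
#' @param ages A `mite_ages` tibble from [element_ages()].
#' @param bin Bin width in years (default 1 Myr).
#' @return A tibble with `bin_start`, `bin_mid`, `count` (class
#'   `mite_age_hist`); the number of saturated/undated elements is carried
#'   in the `excluded` attribute.
#' @export
age_histogram <- function(ages, bin = 1e6) {
  stopifnot(bin > 0)
  ok <- !is.na(ages$T_years)
  excluded <- sum(!ok)
  t <- ages$T_years[ok]
  if (length(t) == 0L) {
    out <- tibble(bin_start = double(), bin_mid = double(), count = integer())
  } else {
    idx <- floor(t / bin)
    tab <- table(factor(idx, levels = 0:max(idx)))
    out <- tibble(bin_start = as.numeric(names(tab)) * bin,
                  bin_mid = (as.numeric(names(tab)) + 0.5) * bin,
                  count = as.integer(tab))
  }
  attr(out, "excluded") <- excluded
  attr(out, "bin") <- bin
  class(out) <- c("mite_age_hist", class(out))
  out
}
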