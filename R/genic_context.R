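# Classification of element insertions relative to gene models, the
# "where did they land" analysis: exon / intron / upstream / downstream
# (within a 2 kb genic window) / intergenic, plus distance profiles
# around transcription start and stop sites.

#' Nearest gene and signed distance for each element
#'
#' Distance is 0 for elements overlapping a gene span, otherwise the gap
#' to the closest span end.  The sign is strand-aware: negative when the
#' element lies 5' of the gene's transcription start.  Ties go to the
#' lexicographically smaller `gene_id`.
#'
#' @param elements Tibble with `element_id`, `seqid`, `start`, `end`.
#' @param genes Gene tibble (see [read_genes_gff3()]).
#' @return A tibble `element_id`, `nearest_gene_id`, `distance`
#'   (absolute gap), `signed_distance`; `NA`s when the element's seqid
#'   carries no gene.
#' @export
nearest_gene <- function(elements, genes) {
  purrr::map(seq_len(nrow(elements)), function(i) {
    x <- elements[i, ]
    g <- genes[genes$seqid == x$seqid, ]
    if (nrow(g) == 0L) {
      return(tibble(element_id = x$element_id,
                    nearest_gene_id = NA_character_,
                    distance = NA_integer_, signed_distance = NA_integer_))
    }
    gap <- pmax(g$start - x$end, x$start - g$end, 0L)
    best <- order(gap, g$gene_id)[1]
    d <- gap[best]
    signed <- d
    if (d > 0L) {
      left_of_gene <- x$end < g$start[best]
      five_prime <- (g$strand[best] == "+") == left_of_gene
      if (five_prime) signed <- -d
    }
    tibble(element_id = x$element_id, nearest_gene_id = g$gene_id[best],
           distance = as.integer(d), signed_distance = as.integer(signed))
  }) |> bind_rows()
}

#' Classify element positions relative to gene models
#'
#' Precedence: exon > intron > upstream/downstream (within
#' `config$genic_window` of the gene) > intergenic.  An element
#' overlapping several genes is classified against the gene with the
#' largest overlap (ties prefer a gene giving an exon call).  Upstream
#' means 5' of the transcription start on the gene's strand, downstream
#' 3' of the transcription stop.
#'
#' @param elements Tibble with `element_id`, `seqid`, `start`, `end`.
#' @param genes Gene tibble with `exons` list-column.
#' @param config A [mite_config()]; supplies `genic_window`.
#' @return A `mite_positions` tibble: `element_id`, `category`,
#'   `nearest_gene_id`, `distance`, `proximal`.
#' @export
classify_position <- function(elements, genes, config = mite_config()) {
  win <- config$genic_window
  out <- purrr::map(seq_len(nrow(elements)), function(i) {
    x <- elements[i, ]
    g <- genes[genes$seqid == x$seqid, ]
    if (nrow(g) == 0L) {
      return(tibble(element_id = x$element_id, category = "intergenic",
                    nearest_gene_id = NA_character_, distance = NA_integer_))
    }
    ovl <- pmin(g$end, x$end) - pmax(g$start, x$start) + 1L
    if (any(ovl > 0L)) {
      cand <- which(ovl > 0L)
      in_exon <- vapply(cand, function(j) {
        ex <- g$exons[[j]]
        any(pmin(ex$end, x$end) - pmax(ex$start, x$start) + 1L > 0L)
      }, TRUE)
      best <- cand[order(-ovl[cand], -in_exon, g$gene_id[cand])[1]]
      cat <- if (in_exon[match(best, cand)]) "exon" else "intron"
      return(tibble(element_id = x$element_id, category = cat,
                    nearest_gene_id = g$gene_id[best], distance = 0L))
    }
    gap <- pmax(g$start - x$end, x$start - g$end, 0L)
    best <- order(gap, g$gene_id)[1]
    d <- gap[best]
    if (d > win) {
      return(tibble(element_id = x$element_id, category = "intergenic",
                    nearest_gene_id = g$gene_id[best],
                    distance = as.integer(d)))
    }
    left_of_gene <- x$end < g$start[best]
    five_prime <- (g$strand[best] == "+") == left_of_gene
    tibble(element_id = x$element_id,
           category = if (five_prime) "upstream" else "downstream",
           nearest_gene_id = g$gene_id[best], distance = as.integer(d))
  }) |> bind_rows()
  out$proximal <- out$category %in% c("exon", "intron", "upstream", "downstream")
  class(out) <- c("mite_positions", class(out))
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Fraction of elements proximal to genes
#'
#' Counts elements classified exon/intron/upstream/downstream and reports
#' the percentage of the total, rounded to the nearest integer -- the
#' headline "within 2 kb of a gene" statistic.
#'
#' @param calls A `mite_positions` tibble from [classify_position()], or
#'   directly the proximal count as a number.
#' @param total Total number of elements (defaults to `nrow(calls)`).
#' @return A one-row tibble with `n_proximal`, `n_total`, `percent`.
#' @examples
#' proximal_fraction(156, 331)
#' @export
proximal_fraction <- function(calls, total = NULL) {
  if (is.numeric(calls)) {
    count <- calls
    if (is.null(total)) stop("total is required when passing a count")
  } else {
    count <- sum(calls$proximal)
    total <- total %||% nrow(calls)
  }
  if (total <= 0) stop("total must be > 0")
  if (count > total) stop("proximal count exceeds total")
  tibble(n_proximal = count, n_total = total,
         percent = round_half_up(100 * count / total))
}

#' Element distance profiles around TSS and TTS
#'
#' Histogram of signed element-midpoint distances to the nearest
#' transcription start site and (separately) the nearest transcription
#' stop site, strand-normalized so negative is always upstream of the
#' site in the direction of transcription.  Elements beyond `window` are
#' excluded.
#'
#' @param elements Tibble with `element_id`, `seqid`, `start`, `end`.
#' @param genes Gene tibble.
#' @param window Half-window in bp (default `config$tss_profile_window`).
#' @param bin Bin width in bp; must divide `window`.
#' @param config A [mite_config()].
#' @return A `mite_tss_profile` tibble: `site` ("TSS"/"TTS"),
#'   `bin_start`, `bin_mid`, `count`.
#' @export
tss_tts_profile <- function(elements, genes, window = NULL, bin = 500L,
                            config = mite_config()) {
  window <- window %||% config$tss_profile_window
  if (bin <= 0) stop("bin must be > 0")
  if (window %% bin != 0) stop("bin must divide window")
  mid <- (elements$start + elements$end) %/% 2L
  site_profile <- function(site_pos_fun) {
    d <- vapply(seq_len(nrow(elements)), function(i) {
      g <- genes[genes$seqid == elements$seqid[i], ]
      if (nrow(g) == 0L) return(NA_integer_)
      pos <- site_pos_fun(g)
      dd <- ifelse(g$strand == "+", mid[i] - pos, pos - mid[i])
      dd[order(abs(dd), g$gene_id)[1]]
    }, NA_integer_)
    breaks <- seq(-window, window, by = bin)
    d <- d[!is.na(d) & d >= -window & d < window]
    counts <- table(cut(d, breaks = breaks, right = FALSE))
    tibble(bin_start = head(breaks, -1L), bin_mid = head(breaks, -1L) + bin / 2,
           count = as.integer(counts))
  }
  tss <- site_profile(function(g) ifelse(g$strand == "+", g$start, g$end))
  tts <- site_profile(function(g) ifelse(g$strand == "+", g$end, g$start))
  out <- bind_rows(mutate(tss, site = "TSS"), mutate(tts, site = "TTS"))
  out <- out[, c("site", "bin_start", "bin_mid", "count")]
  class(out) <- c("mite_tss_profile", class(out))
  out
}
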