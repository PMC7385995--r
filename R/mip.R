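# In-silico insertion-polymorphism (MIP) typing: the computational analog
# of flanking-primer PCR.  A locus is the pair of flanks around one
# insertion; typing an assembly asks whether the flanks are found in
# order and, if so, whether the gap between them holds the element
# (occupied) or nothing but the single pre-insertion target copy (empty).

#' Extract polymorphism loci around elements
#'
#' Flanks are copied verbatim from the source genome.  Elements with less
#' than `flank_len` of sequence on either side are skipped with a
#' warning, mirroring target regions a primer designer would reject.
#'
#' @param elements Element tibble (`element_id`, `seqid`, `start`, `end`).
#' @param genome Source genome tibble.
#' @param flank_len Flank length in bp (default 300).
#' @return A locus tibble: `locus_id`, `seqid`, `start`, `end`,
#'   `element_len`, `left_flank`, `right_flank`.
#' @export
extract_loci <- function(elements, genome, flank_len = 300L) {
  check_genome(genome)
  glen <- setNames(nchar(genome$seq), genome$seqid)
  ok <- elements$start - 1L >= flank_len &
    glen[elements$seqid] - elements$end >= flank_len
  if (any(!ok)) {
    warning(sum(!ok), " element(s) skipped: < ", flank_len, " bp of flank")
  }
  el <- elements[ok, ]
  purrr::map(seq_len(nrow(el)), function(i) {
    x <- el[i, ]
    gseq <- genome_seq(genome, x$seqid)
    tibble(locus_id = x$element_id, seqid = x$seqid,
           start = x$start, end = x$end,
           element_len = x$end - x$start + 1L,
           left_flank = substr(gseq, x$start - flank_len, x$start - 1L),
           right_flank = substr(gseq, x$end + 1L, x$end + flank_len))
  }) |> bind_rows()
}

#' Type polymorphism loci in an assembly
#'
#' Both flanks are located by seed-and-extend alignment (identity >= 0.9
#' over >= 0.8 of the flank).  When both map uniquely to the same
#' sequence and strand in the expected order, the gap between them calls
#' the state: occupied when within +/- `gap_tol` of the element length,
#' empty when at most `empty_max_gap` (an excision leaves a single copy
#' of the target duplication, so the flank matches can even overlap
#' slightly), ambiguous otherwise or when either flank is missing or
#' multi-mapped.
#'
#' @param loci Locus tibble from [extract_loci()].
#' @param assembly Genome tibble to type.
#' @param assembly_id Label recorded in the calls.
#' @param config A [mite_config()].
#' @param scoring An [align_scoring()] object.
#' @param gap_tol Relative tolerance on the occupied gap (default 0.2).
#' @param empty_max_gap Maximum gap, in bp, still called empty.
#' @return A calls tibble: `locus_id`, `assembly_id`, `state`
#'   (occupied/empty/ambiguous), `observed_gap`.
#' @export
type_locus <- function(loci, assembly, assembly_id = "assembly",
                       config = mite_config(), scoring = align_scoring(),
                       gap_tol = 0.2, empty_max_gap = 50L) {
  check_genome(assembly)
  flanks <- setNames(c(loci$left_flank, loci$right_flank),
                     c(paste0(loci$locus_id, "\x01L"),
                       paste0(loci$locus_id, "\x01R")))
  hits <- batch_flank_hits(flanks, assembly, config, scoring)
  hits <- hits[hits$identity >= 0.9 & hits$coverage_query >= 0.8, ]
  purrr::map(seq_len(nrow(loci)), function(i) {
    x <- loci[i, ]
    lh <- hits[hits$flank_id == paste0(x$locus_id, "\x01L"), ]
    rh <- hits[hits$flank_id == paste0(x$locus_id, "\x01R"), ]
    call <- tibble(locus_id = x$locus_id, assembly_id = assembly_id,
                   state = "ambiguous", observed_gap = NA_integer_)
    if (nrow(lh) != 1L || nrow(rh) != 1L) return(call)
    if (lh$seqid != rh$seqid || lh$strand != rh$strand) return(call)
    gap <- if (lh$strand == "+") rh$s_start - lh$s_end - 1L
           else lh$s_start - rh$s_end - 1L
    call$observed_gap <- as.integer(gap)
    if (abs(gap - x$element_len) <= gap_tol * x$element_len) {
      call$state <- "occupied"
    } else if (gap <= empty_max_gap) {
      call$state <- "empty"
    }
    call
  }) |> bind_rows()
}

# Seed-and-extend search of many flanks against one assembly with a
# single k-mer dictionary per strand; returns every local hit per flank
# (not merged across flanks, so multi-mapping is visible).
batch_flank_hits <- function(flanks, assembly, config, scoring) {
  seed <- config$seed_len_assembly
  empty <- tibble(flank_id = character(), seqid = character(),
                  strand = character(), s_start = integer(),
                  s_end = integer(), score = double(), identity = double(),
                  coverage_query = double())
  lens <- nchar(flanks)
  stopifnot(all(lens >= seed))
  km_tbl <- purrr::map(seq_along(flanks), function(i) {
    n <- lens[i]
    tibble(kmer = substring(flanks[[i]], 1:(n - seed + 1L), seed:(n)),
           flank = i, qpos = 1:(n - seed + 1L))
  }) |> bind_rows()
  km_tbl <- km_tbl[!grepl("[^ACGT]", km_tbl$kmer), ]
  if (nrow(km_tbl) == 0L) return(empty)
  uk <- unique(km_tbl$kmer)
  km_tbl$kidx <- match(km_tbl$kmer, uk)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uk))
  sm <- scoring_matrix(scoring)
  out <- list()
  for (gi in seq_len(nrow(assembly))) {
    for (st in c("+", "-")) {
      subj <- if (st == "+") assembly$seq[[gi]] else revcomp(assembly$seq[[gi]])
      ls <- nchar(subj)
      mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
      spos_list <- IRanges::start(mi)
      nh <- lengths(spos_list)
      if (sum(nh) == 0L) next
      hit_k <- rep(seq_along(uk), nh)
      spos <- unlist(spos_list, use.names = FALSE)
      # expand kmer hits to (flank, implied window)
      exp <- km_tbl[km_tbl$kidx %in% hit_k, ]
      joined <- merge(tibble(kidx = hit_k, spos = spos), exp, by = "kidx")
      if (nrow(joined) == 0L) next
      ws <- pmax(1L, joined$spos - (joined$qpos - 1L) - 20L)
      we <- pmin(ls, joined$spos + (lens[joined$flank] - joined$qpos) + 20L)
      for (fi in unique(joined$flank)) {
        sel <- joined$flank == fi
        wins <- IRanges::reduce(IRanges::IRanges(ws[sel], we[sel]),
                                min.gapwidth = 30L)
        q <- Biostrings::DNAString(flanks[[fi]])
        for (w in seq_along(wins)) {
          w1 <- IRanges::start(wins)[w]
          w2 <- IRanges::end(wins)[w]
          pa <- Biostrings::pairwiseAlignment(
            q, Biostrings::DNAString(substr(subj, w1, w2)),
            type = "local", substitutionMatrix = sm,
            gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
          nm <- Biostrings::nmatch(pa)
          nmm <- Biostrings::nmismatch(pa)
          if (nm + nmm == 0L) next
          a <- w1 + Biostrings::start(Biostrings::subject(pa)) - 1L
          b <- w1 + Biostrings::end(Biostrings::subject(pa)) - 1L
          if (st == "-") {
            tmp <- a
            a <- ls - b + 1L
            b <- ls - tmp + 1L
          }
          out[[length(out) + 1L]] <- tibble(
            flank_id = names(flanks)[fi], seqid = assembly$seqid[[gi]],
            strand = st, s_start = a, s_end = b,
            score = Biostrings::score(pa), identity = nm / (nm + nmm),
            coverage_query = Biostrings::width(Biostrings::pattern(pa)) / lens[fi])
        }
      }
    }
  }
  if (length(out) == 0L) empty else bind_rows(out)
}

#' Type loci across several assemblies
#'
#' @param loci Locus tibble from [extract_loci()].
#' @param assemblies Named list of genome tibbles.
#' @param ... Passed on to [type_locus()].
#' @return Row-bound calls for all assemblies.
#' @export
type_loci <- function(loci, assemblies, ...) {
  stopifnot(length(assemblies) >= 1L, !is.null(names(assemblies)))
  purrr::imap(assemblies, function(a, nm) type_locus(loci, a, nm, ...)) |>
    bind_rows()
}

#' Summarize insertion polymorphism across assemblies
#'
#' A locus is *amplified* when at least one assembly gives a
#' non-ambiguous call, *polymorphic* when both occupied and empty states
#' occur among non-ambiguous calls, and *shared-occupied* when occupied
#' in at least two assemblies.  Percentages are rounded to the nearest
#' integer; polymorphic and shared-occupied rates are relative to the
#' amplified loci.
#'
#' @param calls Calls tibble from [type_loci()] covering >= 2 assemblies.
#' @return A `mite_mip` object: list with `per_locus` and a one-row
#'   `summary` (`n_loci`, `n_amplified`, `pct_amplified`,
#'   `n_polymorphic`, `pct_polymorphic`, `n_shared_occupied`,
#'   `pct_shared_occupied`).
#' @export
polymorphism_summary <- function(calls) {
  stopifnot(all(c("locus_id", "assembly_id", "state") %in% names(calls)))
  if (length(unique(calls$assembly_id)) < 2L) {
    stop("polymorphism needs calls from >= 2 assemblies")
  }
  per_locus <- calls |>
    group_by(.data$locus_id) |>
    summarise(
      n_occupied = sum(.data$state == "occupied"),
      n_empty = sum(.data$state == "empty"),
      amplified = any(.data$state != "ambiguous"),
      polymorphic = sum(.data$state == "occupied") > 0L &
        sum(.data$state == "empty") > 0L,
      shared_occupied = sum(.data$state == "occupied") >= 2L,
      .groups = "drop"
    )
  n <- nrow(per_locus)
  na <- sum(per_locus$amplified)
  np <- sum(per_locus$polymorphic & per_locus$amplified)
  ns <- sum(per_locus$shared_occupied & per_locus$amplified)
  summary <- tibble(
    n_loci = n, n_amplified = na,
    pct_amplified = round_half_up(100 * na / n),
    n_polymorphic = np,
    pct_polymorphic = if (na > 0) round_half_up(100 * np / na) else NA_real_,
    n_shared_occupied = ns,
    pct_shared_occupied = if (na > 0) round_half_up(100 * ns / na) else NA_real_
  )
  structure(list(per_locus = per_locus, summary = summary),
            class = "mite_mip")
}

#' @export
print.mite_mip <- function(x, ...) {
  cat("<mite_mip>\n")
  print(x$summary)
  invisible(x)
}
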