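#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one flat list, so a
#' single object can be threaded through discovery, copy-number estimation,
#' genic-context classification, dating, and polymorphism typing.  Defaults
#' encode the structural definition of a MITE (terminal inverted repeats of
#' at least 10 bp, a 2--10 bp target site duplication, total length under
#' 1 kb) and the conventional intact-copy and read-mapping thresholds
#' (80 % identity / 80 % consensus coverage for intact copies; more than
#' 80 % identity over more than 50 % of the read for read mapping).
#'
#' @param min_tir_len Minimum terminal-inverted-repeat length (bp).
#' @param max_tir_len Longest TIR arm scanned for (bp); bounds the scan cost.
#' @param tir_min_identity Minimum Hamming identity between the left TIR arm
#'   and the reverse complement of the right arm.
#' @param tsd_len_range Length-2 integer vector, allowed TSD lengths (bp).
#' @param min_element_len,max_element_len Element length bounds (bp).
#' @param at_rich_threshold AT fraction above which an element is flagged
#'   AT-rich in reports (reported, never filtered on).
#' @param min_family_size Minimum number of clustered candidates required to
#'   seed a family; MITEs are by definition multi-copy, and requiring two
#'   structurally independent hits suppresses chance inverted repeats.
#' @param intact_min_identity,intact_min_coverage Thresholds (inclusive,
#'   `>=`) for counting a consensus hit in an assembly as an intact copy.
#' @param read_min_identity,read_min_coverage Thresholds (exclusive, `>`)
#'   for a read to contribute to the depth profile.
#' @param genic_window Distance (bp) within which an element counts as
#'   gene-proximal (default 2 kb).
#' @param tss_profile_window Window (bp) for TSS/TTS distance profiles.
#' @param substitution_rate_r Neutral substitution rate
#'   (substitutions / site / year) used by the insertion-age clock
#'   `T = k / (2 r)`.
#' @param bootstrap_replicates Bootstrap replicates for tree support.
#' @param seed_len_assembly,seed_len_reads Exact-match seed lengths for the
#'   seed-and-extend search in assemblies and for read mapping.
#' @param rng_seed Default seed used by stochastic operations when no seed
#'   is given explicitly.
#'
#' @return A named list of class `mite_config`.
#' @examples
#' cfg <- mite_config(genic_window = 1500)
#' cfg$genic_window
#' @export
mite_config <- function(min_tir_len = 10L,
                        max_tir_len = 40L,
                        tir_min_identity = 0.9,
                        tsd_len_range = c(2L, 10L),
                        min_element_len = 100L,
                        max_element_len = 1000L,
                        at_rich_threshold = 0.60,
                        min_family_size = 2L,
                        intact_min_identity = 0.80,
                        intact_min_coverage = 0.80,
                        read_min_identity = 0.80,
                        read_min_coverage = 0.50,
                        genic_window = 2000L,
                        tss_profile_window = 5000L,
                        substitution_rate_r = 1.30e-8,
                        bootstrap_replicates = 1000L,
                        seed_len_assembly = 12L,
                        seed_len_reads = 16L,
                        rng_seed = 42L) {
  cfg <- list(
    min_tir_len = as.integer(min_tir_len),
    max_tir_len = as.integer(max_tir_len),
    tir_min_identity = tir_min_identity,
    tsd_len_range = as.integer(tsd_len_range),
    min_element_len = as.integer(min_element_len),
    max_element_len = as.integer(max_element_len),
    at_rich_threshold = at_rich_threshold,
    min_family_size = as.integer(min_family_size),
    intact_min_identity = intact_min_identity,
    intact_min_coverage = intact_min_coverage,
    read_min_identity = read_min_identity,
    read_min_coverage = read_min_coverage,
    genic_window = as.integer(genic_window),
    tss_profile_window = as.integer(tss_profile_window),
    substitution_rate_r = substitution_rate_r,
    bootstrap_replicates = as.integer(bootstrap_replicates),
    seed_len_assembly = as.integer(seed_len_assembly),
    seed_len_reads = as.integer(seed_len_reads),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$min_tir_len >= 1L,
    cfg$max_tir_len >= cfg$min_tir_len,
    length(cfg$tsd_len_range) == 2L,
    cfg$tsd_len_range[1] >= 1L,
    cfg$tsd_len_range[1] <= cfg$tsd_len_range[2],
    cfg$min_element_len < cfg$max_element_len,
    cfg$tir_min_identity > 0, cfg$tir_min_identity <= 1,
    cfg$intact_min_identity > 0, cfg$intact_min_identity <= 1,
    cfg$intact_min_coverage > 0, cfg$intact_min_coverage <= 1,
    cfg$read_min_identity > 0, cfg$read_min_identity <= 1,
    cfg$read_min_coverage > 0, cfg$read_min_coverage <= 1,
    cfg$substitution_rate_r > 0
  )
  structure(cfg, class = c("mite_config", "list"))
}

#' @export
print.mite_config <- function(x, ...) {
  cat("<mite_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Alignment scoring parameters
#'
#' Match/mismatch and affine gap scores used by the pairwise-alignment
#' machinery.  Defaults favour contiguous high-identity hits, the regime in
#' which intact transposon copies are counted.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0); ambiguity codes always score as
#'   mismatches.
#' @param gap_open,gap_extend Affine gap penalties (<= 0).
#' @return A named list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3,
                          gap_open = -5, gap_extend = -2) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = c("align_scoring", "list"))
}
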