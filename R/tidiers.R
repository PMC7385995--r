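# broom-style accessors for the composite result objects.

#' @exportS3Method generics::tidy
tidy.mite_discovery <- function(x, ...) {
  x$elements
}

#' @exportS3Method generics::glance
glance.mite_discovery <- function(x, ...) {
  tibble(n_candidates = nrow(x$candidates),
         n_families = nrow(x$families),
         n_elements = nrow(x$elements),
         mean_at = if (nrow(x$elements)) mean(x$elements$at_fraction) else NA_real_,
         mean_identity = if (nrow(x$elements)) mean(x$elements$identity) else NA_real_)
}

#' @exportS3Method generics::tidy
tidy.mite_families <- function(x, ...) {
  x$families
}

#' @exportS3Method generics::tidy
tidy.mite_mip <- function(x, ...) {
  x$per_locus
}

#' @exportS3Method generics::glance
glance.mite_mip <- function(x, ...) {
  x$summary
}

#' @exportS3Method generics::tidy
tidy.mite_tree <- function(x, ...) {
  tibble(parent = x$edge[, 1], child = x$edge[, 2],
         length = x$edge.length,
         label = c(x$tip.label, x$node.label %||% rep(NA_character_, x$Nnode))[x$edge[, 2]])
}

#' @exportS3Method generics::glance
glance.mite_tree <- function(x, ...) {
  sup <- suppressWarnings(as.numeric(x$node.label))
  tibble(n_tips = length(x$tip.label),
         n_replicates = attr(x, "n_replicates") %||% NA_integer_,
         n_dropped = attr(x, "n_dropped") %||% NA_integer_,
         mean_support = mean(sup, na.rm = TRUE))
}

#' @exportS3Method generics::glance
glance.mite_ages <- function(x, ...) {
  tibble(n = nrow(x), n_saturated = sum(x$saturated),
         mean_k = mean(x$k, na.rm = TRUE),
         mean_T = mean(x$T_years, na.rm = TRUE),
         median_T = stats::median(x$T_years, na.rm = TRUE))
}
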