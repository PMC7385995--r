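# Distance-based phylogenetics: neighbor joining with deterministic
# tie-breaking, and bootstrap bipartition support over column resamples.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration under the Q criterion.  Ties in Q are broken
#' by the smallest pair of node indices (original taxa first, then
#' internal nodes in creation order), so the result is deterministic.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sister branch.
#'
#' @param dm Symmetric numeric matrix (>= 3 taxa) with zero diagonal and
#'   finite entries; dimnames supply taxon labels.
#' @return An unrooted `phylo` tree (ape).
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("neighbor_joining() needs at least 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  nwk <- labels              # newick fragment per active node
  ord <- seq_len(n)          # creation order, for tie-breaking
  D <- dm
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(ord[cand[, 1]], ord[cand[, 2]]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nwk <- c(nwk[keep],
             sprintf("(%s:%.10g,%s:%.10g)", nwk[i], vi, nwk[j], vj))
    ord <- c(ord[keep], max(ord) + 1L)
    D <- D2
  }
  # resolve the final three nodes with the three-point formulas
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[1], v[1], nwk[2], v[2], nwk[3], v[3])
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data K2P + NJ tree, then resamples alignment columns
#' with replacement `config$bootstrap_replicates` times; each replicate is
#' re-distanced and re-built, and support for every internal bipartition
#' of the full tree is the percentage of successful replicates containing
#' it.  Replicates whose distance matrix contains a saturated pair are
#' re-drawn up to 10 times, then dropped (and counted).
#'
#' @param msa MSA tibble (`taxon`, `aligned`) with >= 4 taxa.
#' @param config A [mite_config()].
#' @param seed Integer seed for the resampling; `NULL` uses
#'   `config$rng_seed`.
#' @return A `mite_tree` object: the `phylo` tree with `node.label` set to
#'   bootstrap percentages and attributes `n_replicates`, `n_dropped`.
#' @export
bootstrap_support <- function(msa, config = mite_config(), seed = NULL) {
  stopifnot(nrow(msa) >= 4L)
  set.seed(seed %||% config$rng_seed)
  m <- encode_dna_matrix(msa$aligned)
  rownames(m) <- msa$taxon
  D <- k2p_matrix_encoded(m)
  if (any(is.na(D))) stop("saturated pair(s) in the full alignment")
  dimnames(D) <- list(msa$taxon, msa$taxon)
  full <- neighbor_joining(D)
  L <- ncol(m)
  B <- config$bootstrap_replicates
  boots <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    tr <- NULL
    for (try in seq_len(10L)) {
      cols <- sample.int(L, L, replace = TRUE)
      Db <- k2p_matrix_encoded(m[, cols, drop = FALSE])
      if (any(is.na(Db))) next
      dimnames(Db) <- list(msa$taxon, msa$taxon)
      tr <- neighbor_joining(Db)
      break
    }
    if (is.null(tr)) dropped <- dropped + 1L else boots[[b]] <- tr
  }
  boots <- boots[!vapply(boots, is.null, TRUE)]
  nb <- length(boots)
  if (nb > 0L) {
    counts <- ape::prop.clades(full, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    full$node.label <- as.character(round(100 * counts / nb))
  } else {
    full$node.label <- rep("0", full$Nnode)
  }
  structure(full, n_replicates = nb, n_dropped = dropped,
            class = c("mite_tree", class(full)))
}

#' Write a tree (with supports as internal node labels) to Newick
#'
#' @param tree A `phylo` or `mite_tree` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
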