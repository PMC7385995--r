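#' Read a genome (or any sequence set) from FASTA
#'
#' Residues are uppercased and line breaks removed; record order is
#' preserved.  An empty file yields an empty tibble rather than an error so
#' that pipelines compose.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seqid`, `seq`, `length`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    return(tibble(seqid = character(), seq = character(), length = integer()))
  }
  if (any(Biostrings::width(ss) == 0L)) {
    stop("FASTA record with empty sequence in ", path)
  }
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  tibble(seqid = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with `seqid` and `seq` columns (e.g. from
#'   [read_genome()]), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- tibble(seqid = names(x) %||% as.character(seq_along(x)), seq = unname(x))
  }
  ss <- Biostrings::BStringSet(setNames(x$seq, x$seqid))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene models from GFF3
#'
#' Builds one record per `gene` feature; `exon` features are attached to
#' their parent gene, resolving one intermediate transcript layer
#' (gene -> mRNA -> exon) when present.  Exons from multiple transcripts
#' are flattened into a non-overlapping, sorted set.  Genes without any
#' exon child get a single exon equal to their span.  Coordinates stay in
#' the GFF convention (1-based, inclusive) throughout the package.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand`, and a list-column `exons` of tibbles with `start`, `end`.
#' @export
read_genes_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(gene_id = character(), seqid = character(),
                  start = integer(), end = integer(), strand = character(),
                  exons = list()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) != 9L
  if (any(bad)) stop("malformed GFF3 line(s): ", which(bad)[1])
  gff <- tibble(
    seqid = vapply(f, `[[`, "", 1L),
    type = vapply(f, `[[`, "", 3L),
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    attr = vapply(f, `[[`, "", 9L)
  )
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  genes <- gff[gff$type == "gene", ]
  genes$gene_id <- get_attr(genes$attr, "ID")
  if (anyNA(genes$gene_id)) stop("gene feature without an ID attribute")
  # transcript layer: map transcript ID -> gene ID
  tx <- gff[gff$type %in% c("mRNA", "transcript"), ]
  tx_id <- get_attr(tx$attr, "ID")
  tx_parent <- get_attr(tx$attr, "Parent")
  tx_map <- setNames(tx_parent, tx_id)
  exons <- gff[gff$type == "exon", ]
  if (nrow(exons) > 0L) {
    parent <- get_attr(exons$attr, "Parent")
    parent_gene <- ifelse(parent %in% names(tx_map), unname(tx_map[parent]), parent)
    unknown <- !(parent_gene %in% genes$gene_id)
    if (any(unknown)) {
      stop("exon with unknown Parent: ", parent[which(unknown)[1]])
    }
    exons$gene_id <- parent_gene
  }
  exon_list <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(ex) == 0L) {
      return(tibble(start = g$start, end = g$end))
    }
    if (any(ex$start < g$start | ex$end > g$end)) {
      stop("exon outside parent span for gene ", g$gene_id)
    }
    ir <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    tibble(start = IRanges::start(ir), end = IRanges::end(ir))
  })
  tibble(gene_id = genes$gene_id, seqid = genes$seqid,
         start = genes$start, end = genes$end,
         strand = genes$strand, exons = exon_list)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_genes_gff3()]: emits one `gene` feature plus its
#' `exon` children per record.
#'
#' @param genes Gene tibble as produced by [read_genes_gff3()] or
#'   [simulate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tmitescout\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$seqid, g$start, g$end, g$strand, g$gene_id), con)
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tmitescout\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$seqid, ex$start[j], ex$end[j], g$strand,
                         g$gene_id, j, g$gene_id), con)
    }
  }
  invisible(path)
}

#' Write MITE candidates or elements to GFF3
#'
#' Emits feature type `MITE` with attributes carrying the element id,
#' family, TIR length, TSD sequence and AT fraction.
#'
#' @param candidates Candidate/element tibble (see [find_tir_candidates()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(candidates))) {
    x <- candidates[i, ]
    attrs <- sprintf("ID=%s", x$element_id)
    if (!is.null(candidates$family_id) && !is.na(x$family_id)) {
      attrs <- paste0(attrs, ";family_id=", x$family_id)
    }
    attrs <- paste0(attrs, ";tir_len=", x$tir_len)
    if (!is.na(x$tsd)) attrs <- paste0(attrs, ";tsd=", x$tsd)
    attrs <- paste0(attrs, ";at_fraction=", sprintf("%.4f", x$at_fraction))
    strand <- if (!is.null(candidates$strand)) x$strand else "+"
    writeLines(sprintf("%s\tmitescout\tMITE\t%d\t%d\t.\t%s\t.\t%s",
                       x$seqid, x$start, x$end, strand, attrs), con)
  }
  invisible(path)
}

#' Read MITE annotations written by [write_candidates_gff3()]
#'
#' @param path Path to the GFF3 file.
#' @return A tibble with `element_id`, `seqid`, `start`, `end`, `strand`,
#'   `family_id`, `tir_len`, `tsd`, `at_fraction`.
#' @export
read_candidates_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(element_id = character(), seqid = character(),
                  start = integer(), end = integer(), strand = character(),
                  family_id = character(), tir_len = integer(),
                  tsd = character(), at_fraction = double()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr <- vapply(f, `[[`, "", 9L)
  pick <- function(key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  tibble(
    element_id = pick("ID"),
    seqid = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 4L)),
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    family_id = pick("family_id"),
    tir_len = as.integer(pick("tir_len")),
    tsd = pick("tsd"),
    at_fraction = as.numeric(pick("at_fraction"))
  )
}

#' Write element intervals to BED
#'
#' BED is 0-based half-open, so `start - 1` is written.
#'
#' @param x Tibble with `seqid`, `start`, `end` and optionally
#'   `element_id`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- x$element_id %||% rep(".", nrow(x))
  strand <- x$strand %||% rep("+", nrow(x))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   x$seqid, x$start - 1L, x$end, name, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read BED intervals
#'
#' @param path Path to a BED file.
#' @return Tibble with `seqid`, `start`, `end` (1-based inclusive),
#'   `element_id`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(seqid = character(), start = integer(), end = integer(),
                  element_id = character(), strand = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    seqid = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 2L)) + 1L,
    end = as.integer(vapply(f, `[[`, "", 3L)),
    element_id = vapply(f, function(x) if (length(x) >= 4) x[[4]] else ".", ""),
    strand = vapply(f, function(x) if (length(x) >= 6) x[[6]] else "+", "")
  )
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' @param path Path to the reads file; format chosen by extension
#'   (`.fastq`/`.fq` vs anything else).
#' @return Tibble with `read_id`, `seq`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read_id = sub("\\s.*$", "", names(ss)),
         seq = unname(as.character(ss)))
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a multiple alignment as aligned FASTA
#'
#' @param msa Tibble with `taxon` and gapped `aligned` columns.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, an MSA tibble.
#' @export
write_msa_fasta <- function(msa, path) {
  write_fasta(tibble(seqid = msa$taxon, seq = msa$aligned), path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  x <- read_genome(path)
  if (nrow(x) > 0L && length(unique(x$length)) != 1L) {
    stop("aligned FASTA rows differ in length")
  }
  tibble(taxon = x$seqid, aligned = x$seq)
}
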