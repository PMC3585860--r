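#' @importFrom stats optimize optim pchisq pt qt rbinom rexp rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

ALIGNMENT_ALPHABET <- c("A", "C", "G", "T", "U", "N", "-", "?")

new_gene_alignment <- function(gene, seqs) {
  structure(list(gene = gene, seqs = seqs, length = unique(nchar(seqs))),
            class = "gene_alignment")
}

#' Construct a gene alignment from named sequences
#'
#' @param seqs Named character vector, one aligned sequence per taxon.
#' @param gene Gene name.
#' @return A `"gene_alignment"` object with fields `gene`, `seqs`, `length`.
#' @export
gene_alignment <- function(seqs, gene = "gene") {
  if (!length(seqs)) stop("alignment has no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named by taxon")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon labels in gene '", gene, "'")
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("unequal sequence lengths in gene '", gene, "': not an alignment")
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 ALIGNMENT_ALPHABET)
  if (length(bad))
    stop("invalid characters in gene '", gene, "': ", paste(bad, collapse = " "))
  new_gene_alignment(gene, seqs)
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("Gene alignment '%s': %d taxa x %d columns\n",
              x$gene, length(x$seqs), x$length))
  invisible(x)
}

#' Read a FASTA alignment
#'
#' The taxon label is the first whitespace-delimited token of each header.
#' Sequences are upper-cased on read.
#'
#' @param path Path to a FASTA file.
#' @param gene Gene name recorded on the alignment (default: file base name).
#' @return A `"gene_alignment"`.
#' @export
read_fasta <- function(path, gene = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (no leading '>'): ", path)
  idx <- cumsum(hdr)
  labels <- vapply(strsplit(sub("^>\\s*", "", lines[hdr]), "\\s+"),
                   `[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1))
  if (length(seqs) != length(labels)) stop("FASTA record with no sequence in ", path)
  names(seqs) <- labels
  gene_alignment(seqs, gene = gene)
}

#' Write a FASTA alignment
#'
#' @param alignment A `"gene_alignment"` (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path, width = 70) {
  seqs <- if (inherits(alignment, "gene_alignment")) alignment$seqs else alignment
  out <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", nm), body)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Rows are the union of taxa over all genes; a taxon absent from a gene is
#' filled with `?` across that gene's partition. The missing-data fraction
#' counts only those absent taxon-gene cells (gap characters inside present
#' sequences are indels, not missing data) over taxa x total length.
#'
#' @param genes List of `"gene_alignment"` objects with distinct gene names.
#' @return A `"supermatrix"`: `seqs` (named character vector), `partitions`
#'   (data frame `gene`, `start`, `end`, 1-based inclusive), and
#'   `missing_fraction`.
#' @export
concatenate_genes <- function(genes) {
  if (!length(genes)) stop("need at least one gene alignment")
  if (inherits(genes, "gene_alignment")) genes <- list(genes)
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_alignment")))
  gnames <- vapply(genes, `[[`, character(1), "gene")
  if (anyDuplicated(gnames))
    stop("duplicate gene names: ",
         paste(unique(gnames[duplicated(gnames)]), collapse = ", "))
  taxa <- unique(unlist(lapply(genes, function(g) names(g$seqs))))
  lens <- vapply(genes, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  rows <- setNames(rep("", length(taxa)), taxa)
  missing_cells <- 0
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    fill <- strrep("?", g$length)
    present <- taxa %in% names(g$seqs)
    missing_cells <- missing_cells + sum(!present) * g$length
    block <- ifelse(present, g$seqs[taxa], fill)
    rows <- paste0(rows, block)
  }
  names(rows) <- taxa
  structure(list(
    seqs = rows,
    partitions = data.frame(gene = gnames, start = starts, end = ends,
                            stringsAsFactors = FALSE),
    missing_fraction = missing_cells / (length(taxa) * sum(lens))
  ), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d positions, %d partitions, %.1f%% missing\n",
              length(x$seqs), nchar(x$seqs[[1]]), nrow(x$partitions),
              100 * x$missing_fraction))
  invisible(x)
}

#' Write a RAxML-style partition file
#'
#' Emits lines of the form `DNA, <gene> = <start>-<end>`.
#'
#' @param supermatrix A `"supermatrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(supermatrix, path) {
  p <- supermatrix$partitions
  writeLines(sprintf("DNA, %s = %d-%d", p$gene, p$start, p$end), path)
  invisible(path)
}

#' Uncorrected p-distance matrix with complete deletion
#'
#' Columns containing a gap (`-`), missing (`?`) or ambiguous (`N`) character
#' in any row are removed once, globally; each pairwise distance is the
#' proportion of differing sites over the retained columns.
#'
#' @param alignment A `"gene_alignment"` with at least two taxa.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "gene_alignment"))
  if (length(alignment$seqs) < 2L) stop("need at least 2 taxa")
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(m) <- names(alignment$seqs)
  keep <- colSums(m == "-" | m == "?" | m == "N") == 0L
  if (!any(keep))
    stop("complete deletion removed every column; no sites left")
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
  }
  d
}

#' Mean between-cluster distances
#'
#' Averages pairwise distances over all inter-cluster taxon pairs, for every
#' pair of clusters; also reports the global minimum and maximum cluster-pair
#' mean (the "between-STU distance range").
#'
#' @param dist Symmetric distance matrix with taxon dimnames.
#' @param clusters Named vector mapping every taxon in `dist` to a cluster id.
#' @return Data frame `cluster_a`, `cluster_b`, `n_pairs`, `mean_dist`, with
#'   attributes `min` and `max` (NA when fewer than two clusters).
#' @export
between_group_mean_distance <- function(dist, clusters) {
  taxa <- rownames(dist)
  if (is.null(taxa)) stop("distance matrix must carry taxon dimnames")
  if (!all(taxa %in% names(clusters)))
    stop("unassigned taxa: ",
         paste(setdiff(taxa, names(clusters)), collapse = ", "))
  cl <- as.character(clusters[taxa])
  ids <- unique(cl)
  if (any(!ids %in% cl)) stop("cluster with no taxa")
  pairs <- if (length(ids) >= 2) utils::combn(ids, 2, simplify = FALSE) else list()
  res <- do.call(rbind, lapply(pairs, function(p) {
    block <- dist[cl == p[1], cl == p[2], drop = FALSE]
    data.frame(cluster_a = p[1], cluster_b = p[2],
               n_pairs = length(block), mean_dist = mean(block),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(cluster_a = character(), cluster_b = character(),
                      n_pairs = integer(), mean_dist = numeric())
  attr(res, "min") <- if (nrow(res)) min(res$mean_dist) else NA_real_
  attr(res, "max") <- if (nrow(res)) max(res$mean_dist) else NA_real_
  res
}
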