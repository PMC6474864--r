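#' Gene-level count matrix with sample metadata
#'
#' Lightweight container used throughout the package: an integer matrix of
#' gene counts with a per-sample metadata frame and library sizes equal to
#' the column sums.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene_id), samples in columns.
#' @param meta data.frame with one row per sample; must contain `sample_id`
#'   and `tissue` (`donor`/`pdx`); `patient_id`, `pipeline`, `passage`
#'   optional.
#' @return List of class `pdx_counts`: `counts`, `meta`, `library_sizes`.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts))) colnames(counts) <- meta$sample_id
  if (!all(colnames(counts) == meta$sample_id))
    stop("meta rows must match count columns (sample_id order)")
  structure(list(counts = counts, meta = meta,
                 library_sizes = colSums(counts)), class = "pdx_counts")
}

#' @export
print.pdx_counts <- function(x, ...) {
  cat(sprintf("pdx_counts: %d genes x %d samples (median library %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(median(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
`[.pdx_counts` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(j)) j <- match(j, x$meta$sample_id)
  count_matrix(x$counts[i, j, drop = FALSE], x$meta[j, , drop = FALSE])
}

#' Build a gene k-mer map for pseudo-alignment
#'
#' Maps every canonical k-mer of the graft transcript set to the genes that
#' contain it; used by [assign_reads()] to place retained reads.
#'
#' @param graft Named character vector of transcripts, FASTA path, or
#'   `DNAStringSet`.
#' @param k K-mer size (default 25).
#' @return Object of class `gene_kmer_map`.
#' @export
build_gene_kmer_map <- function(graft, k = 25L) {
  graft <- as_seq_chr(graft)
  ptr <- .gene_map_build(graft, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 gene_ids = names(graft) %||%
                   sprintf("gene%d", seq_along(graft))),
            class = "gene_kmer_map")
}

#' Assign read pairs to genes by k-mer vote
#'
#' Candidate genes are scored by the number of the pair's k-mer positions
#' they contain; the read is assigned to the unique maximum. Ties and reads
#' matching no indexed k-mer are unassigned (`NA`).
#'
#' @param reads List with `r1`, `r2` (and optionally `read_id`), or character
#'   vector of mate-1 sequences.
#' @param gene_map A `gene_kmer_map`.
#' @param r2 Optional mate-2 vector when `reads` is a character vector.
#' @return Character vector of gene_ids (NA = unassigned), one per pair.
#' @export
assign_reads <- function(reads, gene_map, r2 = NULL) {
  stopifnot(inherits(gene_map, "gene_kmer_map"))
  if (is.character(reads)) {
    reads <- list(r1 = unname(reads),
                  r2 = if (is.null(r2)) rep(NA_character_, length(reads))
                       else unname(r2))
  }
  idx <- .assign_reads(reads$r1, reads$r2, gene_map$ptr)
  gene_map$gene_ids[idx]
}

#' Count assigned reads for one sample
#'
#' @param reads Read list for one sample (see [assign_reads()]).
#' @param gene_map A `gene_kmer_map`.
#' @return List: `counts` (named integer vector over all mapped genes, summing
#'   to the number of assigned reads), `n_assigned`, `n_unassigned`.
#' @export
count_sample <- function(reads, gene_map) {
  assigned <- assign_reads(reads, gene_map)
  tab <- table(factor(assigned, levels = gene_map$gene_ids))
  counts <- setNames(as.vector(tab, mode = "integer"), gene_map$gene_ids)
  list(counts = counts, n_assigned = sum(!is.na(assigned)),
       n_unassigned = sum(is.na(assigned)))
}
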