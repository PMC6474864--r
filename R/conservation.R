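#' Per-gene conservation scores from a per-base score track
#'
#' Averages per-base conservation scores (phastCons-style, in \[0,1\]) over
#' the covered bases of each gene interval. Bases without a score are
#' excluded from both numerator and denominator; genes with no covered base
#' are reported as missing. The supplied intervals define coverage: pass exon
#' unions or whole gene bodies as desired.
#'
#' @param scores A `GRanges` with a numeric `score` column, or the path to a
#'   bedGraph file (chrom, start, end, score; 0-based half-open).
#' @param gene_intervals A named `GRanges` (names = gene_id) or a data.frame
#'   with columns chrom, start, end, gene_id (0-based half-open).
#' @return data.frame: gene_id, score (NA when uncovered), covered_bases.
#' @export
gene_conservation <- function(scores, gene_intervals) {
  scores <- as_score_granges(scores)
  gi <- as_gene_granges(gene_intervals)
  if (any(scores$score < 0 | scores$score > 1))
    stop("conservation scores must lie in [0, 1]")
  hits <- GenomicRanges::findOverlaps(gi, scores)
  num <- den <- numeric(length(gi))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(gi[S4Vectors::queryHits(hits)],
                                    scores[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    sc <- scores$score[S4Vectors::subjectHits(hits)]
    num <- as.vector(tapply(w * sc, factor(S4Vectors::queryHits(hits),
                                           levels = seq_along(gi)),
                            sum, default = 0))
    den <- as.vector(tapply(w, factor(S4Vectors::queryHits(hits),
                                      levels = seq_along(gi)),
                            sum, default = 0))
  }
  data.frame(gene_id = names(gi),
             score = ifelse(den > 0, num / den, NA_real_),
             covered_bases = den, stringsAsFactors = FALSE, row.names = NULL)
}

as_score_granges <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- rtracklayer::import(x, format = "bedGraph")
  }
  if (!methods::is(x, "GRanges") || is.null(x$score))
    stop("scores must be a bedGraph path or a GRanges with a score column")
  x
}

as_gene_granges <- function(x) {
  if (is.data.frame(x)) {
    gr <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1, x$end))
    names(gr) <- x$gene_id
    return(gr)
  }
  if (!methods::is(x, "GRanges") || is.null(names(x)))
    stop("gene_intervals must be a named GRanges or a data.frame")
  x
}

#' Compare conservation of flagged genes against the background
#'
#' Tests whether genes flagged by the pipeline-sensitivity control sit in
#' more conserved sequence than the remaining genes, using a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test on per-gene conservation scores.
#'
#' @param flagged_genes Character vector of flagged gene ids.
#' @param all_genes Character vector of the full tested gene universe.
#' @param scores Named numeric vector of per-gene conservation scores (or a
#'   data.frame from [gene_conservation()]).
#' @return List: `mean_flagged`, `mean_background`, `p_value` (NA when either
#'   group is empty), `n_flagged`, `n_background`, and the two score vectors
#'   (`flagged_scores`, `background_scores`) for plotting.
#' @export
compare_flagged_vs_background <- function(flagged_genes, all_genes, scores) {
  if (is.data.frame(scores))
    scores <- setNames(scores$score, scores$gene_id)
  flagged <- scores[intersect(flagged_genes, all_genes)]
  background <- scores[setdiff(all_genes, flagged_genes)]
  flagged <- flagged[!is.na(flagged)]
  background <- background[!is.na(background)]
  p <- if (length(flagged) > 0 && length(background) > 0)
    suppressWarnings(wilcox.test(flagged, background)$p.value)
  else NA_real_
  list(mean_flagged = if (length(flagged)) mean(flagged) else NA_real_,
       mean_background = if (length(background)) mean(background)
                         else NA_real_,
       p_value = p, n_flagged = length(flagged),
       n_background = length(background),
       flagged_scores = flagged, background_scores = background)
}
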