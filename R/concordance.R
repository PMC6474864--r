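#' Donor-PDX pairwise expression correlations
#'
#' Pearson correlation (on log2 CPM) between each donor sample and its
#' matched PDX, over genes not excluded; used to quantify how much removing a
#' gene set (e.g. called XDGs) tightens donor-PDX transcriptome agreement.
#'
#' @param log_expr Numeric matrix of log-scale expression
#'   (genes x samples), e.g. `cpm(counts, log = TRUE)`.
#' @param pairs data.frame with columns `donor` and `pdx` (sample names).
#' @param exclude Optional character vector of gene ids to drop.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `per_pair` (named numeric), `mean_r`, `n_genes`.
#' @export
pair_correlations <- function(log_expr, pairs, exclude = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- setdiff(rownames(log_expr), exclude)
  if (length(keep) < 2) stop("fewer than 2 genes left after exclusion")
  m <- log_expr[keep, , drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    cor(m[, pairs$donor[i]], m[, pairs$pdx[i]], method = method)
  }, numeric(1))
  names(r) <- pairs$donor
  list(per_pair = r, mean_r = mean(r), n_genes = length(keep))
}

#' Dendrogram alignment of donor-PDX pairs
#'
#' Samples are clustered by average-linkage hierarchical clustering on the
#' distance `1 - Pearson r` between expression columns. A pair is "aligned"
#' when the donor and its PDX are merged with each other before either merges
#' with any other sample (they are siblings / first merge partners in the
#' dendrogram).
#'
#' @inheritParams pair_correlations
#' @return List: `n_aligned`, `n_pairs`, `aligned` (named logical),
#'   `hclust`, `newick` (serialized tree).
#' @export
cluster_alignment <- function(log_expr, pairs, exclude = NULL) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  keep <- setdiff(rownames(log_expr), exclude)
  m <- log_expr[keep, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  leaves <- hc$labels
  aligned <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- match(pairs$donor[i], leaves)
    b <- match(pairs$pdx[i], leaves)
    # siblings iff some merge row joins exactly these two singletons
    any(apply(hc$merge, 1, function(row)
      all(sort(row) == sort(c(-a, -b)))))
  }, logical(1))
  names(aligned) <- pairs$donor
  list(n_aligned = sum(aligned), n_pairs = nrow(pairs), aligned = aligned,
       hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Association of PDX gene expression with passage number
#'
#' Per-gene Spearman correlation of PDX expression with passage, with
#' two-sided p-values (exact null for n <= 9 without ties, t-approximation
#' otherwise) and BH adjustment. Genes with constant expression have an
#' undefined rank correlation and are reported as missing, excluded from the
#' adjustment.
#'
#' @param pdx_expr Log-expression matrix for PDX samples only
#'   (genes x samples).
#' @param passages Integer vector of passage numbers, one per column.
#' @param fdr_threshold FDR level reported in the summary (default 0.30).
#' @return List: `table` (gene_id, rho, pvalue, fdr), `n_significant` at the
#'   threshold, `fdr_threshold`.
#' @export
passage_association <- function(pdx_expr, passages, fdr_threshold = 0.30) {
  stopifnot(ncol(pdx_expr) == length(passages))
  if (length(unique(passages)) < 4)
    stop("need at least 4 distinct passage values")
  exact <- ncol(pdx_expr) <= 9
  res <- t(apply(pdx_expr, 1, function(y) {
    if (stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(y, passages, method = "spearman",
                                    exact = exact))
    c(unname(ct$estimate), ct$p.value)
  }))
  tab <- data.frame(gene_id = rownames(pdx_expr), rho = res[, 1],
                    pvalue = res[, 2],
                    fdr = benjamini_hochberg(res[, 2]),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab,
       n_significant = sum(tab$fdr < fdr_threshold, na.rm = TRUE),
       fdr_threshold = fdr_threshold)
}
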