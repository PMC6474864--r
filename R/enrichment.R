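#' Hypergeometric overlap enrichment between two gene lists
#'
#' Upper-tail hypergeometric test for the overlap of two gene lists within an
#' explicit universe: `p = P(X >= k)` for
#' `X ~ Hypergeometric(N = |universe|, K = |a|, n = |b|)`, plus the sample
#' odds ratio of the 2x2 overlap table (Haldane +0.5 correction on zero
#' cells, flagged).
#'
#' @param list_a,list_b Character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe Character vector defining the tested gene universe.
#' @return List: `k_overlap`, `p_value`, `odds_ratio`, `n_a`, `n_b`,
#'   `n_universe`, `haldane` (TRUE when the 0.5 correction was applied).
#' @export
hypergeom_overlap <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  out_a <- setdiff(list_a, universe)
  out_b <- setdiff(list_b, universe)
  if (length(out_a) || length(out_b))
    stop("elements outside the universe: ",
         paste(head(c(out_a, out_b), 10), collapse = ", "))
  N <- length(universe)
  K <- length(list_a)
  n <- length(list_b)
  k <- length(intersect(list_a, list_b))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tab <- c(k, K - k, n - k, N - K - n + k)
  haldane <- any(tab == 0)
  if (haldane) tab <- tab + 0.5
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  list(k_overlap = k, p_value = p, odds_ratio = or, n_a = K, n_b = n,
       n_universe = N, haldane = haldane)
}

#' Fisher's exact enrichment of a DEG set in gene families
#'
#' Two-sided Fisher's exact test (point-probability method) of each family's
#' 2x2 membership table against the DEG set, with BH adjustment across
#' families. Family definitions are user supplied.
#'
#' @param deg_set Character vector of differentially expressed gene ids.
#' @param family_sets Named list of character vectors (one per family).
#' @param universe Character vector; all ids must belong to it.
#' @return data.frame: family, n_family, k_overlap, odds_ratio (sample
#'   cross-product, Haldane-corrected on zero cells), p_value, fdr.
#' @export
fisher_family_enrichment <- function(deg_set, family_sets, universe) {
  universe <- unique(universe)
  deg_set <- unique(deg_set)
  bad <- setdiff(deg_set, universe)
  if (length(bad))
    stop("DEG ids outside the universe: ",
         paste(head(bad, 10), collapse = ", "))
  rows <- lapply(names(family_sets), function(fam) {
    fs <- unique(family_sets[[fam]])
    out <- setdiff(fs, universe)
    if (length(out))
      stop("family '", fam, "' has ids outside the universe: ",
           paste(head(out, 10), collapse = ", "))
    k <- length(intersect(deg_set, fs))
    tab <- matrix(c(k, length(fs) - k,
                    length(deg_set) - k,
                    length(universe) - length(fs) - length(deg_set) + k),
                  nrow = 2)
    ft <- fisher.test(tab)
    or_tab <- if (any(tab == 0)) tab + 0.5 else tab  # Haldane on zero cells
    data.frame(family = fam, n_family = length(fs), k_overlap = k,
               odds_ratio = (or_tab[1, 1] * or_tab[2, 2]) /
                 (or_tab[1, 2] * or_tab[2, 1]),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  out
}

#' Spearman correlation of fold changes with a signature
#'
#' Correlates per-gene log2 fold changes (e.g. of XDGs) with external
#' signature scores over the intersecting genes.
#'
#' @param xdg_log2fc Named numeric vector of log2 fold changes.
#' @param signature_scores Named numeric vector of signature scores.
#' @return List: `rho`, `p_value`, `n_genes` (intersection size).
#' @export
signature_correlation <- function(xdg_log2fc, signature_scores) {
  common <- intersect(names(xdg_log2fc), names(signature_scores))
  if (length(common) < 5)
    stop("need at least 5 overlapping genes, got ", length(common))
  ct <- suppressWarnings(cor.test(xdg_log2fc[common],
                                  signature_scores[common],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_genes = length(common))
}
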