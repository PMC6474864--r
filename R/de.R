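#' Counts per million
#'
#' @param counts A `pdx_counts` or numeric matrix.
#' @param lib Library sizes (defaults to column sums).
#' @param log If `TRUE`, return `log2(CPM + prior)`.
#' @param prior Prior count added on the CPM scale before logging.
#' @return Numeric matrix of CPM values.
#' @export
cpm <- function(counts, lib = NULL, log = FALSE, prior = 0.5) {
  m <- if (inherits(counts, "pdx_counts")) counts$counts else as.matrix(counts)
  lib <- lib %||% colSums(m)
  if (any(lib <= 0)) stop("library sizes must be positive")
  out <- sweep(m, 2, lib, "/") * 1e6
  if (log) log2(out + prior) else out
}

#' Remove genes with low average expression
#'
#' Retains genes whose mean counts-per-million across all samples is at least
#' `min_avg_cpm` (default 2), preserving gene order.
#'
#' @param counts A `pdx_counts`.
#' @param min_avg_cpm Mean-CPM threshold.
#' @return Filtered `pdx_counts`, with the kept gene ids in attribute
#'   `kept_genes`.
#' @export
filter_low_expression <- function(counts, min_avg_cpm = 2) {
  stopifnot(inherits(counts, "pdx_counts"))
  keep <- rowMeans(cpm(counts)) >= min_avg_cpm
  if (!any(keep)) stop("all genes removed by the expression filter")
  out <- counts[keep, ]
  attr(out, "kept_genes") <- rownames(counts$counts)[keep]
  out
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for count data. The reference sample is the
#' one whose 75th-percentile count fraction is closest to the mean across
#' samples. For each sample, gene-wise log2 ratios (M) against the reference
#' and average log2 abundances (A) are computed over genes with positive
#' counts in both; the most extreme 30% of M on each side and 5% of A on each
#' side are trimmed; the factor is the inverse-variance weighted mean of the
#' remaining M values (delta-method binomial weights), exponentiated and
#' rescaled so factors have geometric mean 1.
#'
#' @param counts A `pdx_counts` or matrix.
#' @param logratio_trim,abs_trim Two-sided trim fractions on M and A.
#' @return List of class `tmm_factors`: `factors` (named, geometric mean 1)
#'   and `effective_lib` (= library size x factor).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  m <- if (inherits(counts, "pdx_counts")) counts$counts else as.matrix(counts)
  lib <- colSums(m)
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(m)[lib == 0], collapse = ", "))
  uq <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    tmm_pair(m[, s], m[, ref], lib[s], lib[ref], logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = setNames(f, colnames(m)),
                 effective_lib = setNames(f * lib, colnames(m)),
                 ref_sample = colnames(m)[ref]),
            class = "tmm_factors")
}

tmm_pair <- function(y, yr, n, nr, logratio_trim, abs_trim) {
  ok <- y > 0 & yr > 0
  y <- y[ok]; yr <- yr[ok]
  if (length(y) == 0) return(1)
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)  # delta-method var of M
  loM <- quantile(M, logratio_trim); hiM <- quantile(M, 1 - logratio_trim)
  loA <- quantile(A, abs_trim); hiA <- quantile(A, 1 - abs_trim)
  keep <- M >= loM & M <= hiM & A >= loA & A <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# Model matrix for a (possibly paired) two-condition contrast.
de_design <- function(meta, condition, ref_level, paired_by) {
  cond <- factor(meta[[condition]])
  if (nlevels(cond) != 2) stop("'", condition, "' must have exactly 2 levels")
  if (!is.null(ref_level)) cond <- stats::relevel(cond, ref_level)
  if (!is.null(paired_by)) {
    block <- factor(meta[[paired_by]])
    tab <- table(block, cond)
    bad <- rownames(tab)[rowSums(tab != 1) > 0]
    if (length(bad))
      stop("unpaired ", paired_by, ": ", paste(bad, collapse = ", "))
    full <- stats::model.matrix(~ block + cond)
    reduced <- stats::model.matrix(~ block)
  } else {
    full <- stats::model.matrix(~ cond)
    reduced <- stats::model.matrix(~ 1, data = data.frame(row.names =
                                                            seq_along(cond)))
  }
  list(full = full, reduced = reduced, cond = cond)
}

# NB IRLS fit with log link, fixed dispersion phi and offset.
# Returns coefficients, deviance and convergence flag.
nb_glm_fit <- function(y, X, offset, phi, maxit = 50, tol = 1e-8) {
  eta <- log(pmax(y, 0) + 0.5)
  dev <- Inf
  beta <- NULL
  conv <- FALSE
  for (it in seq_len(maxit)) {
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta <- fit$coefficients
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    newdev <- nb_deviance(y, mu, phi)
    if (is.finite(newdev) && abs(dev - newdev) <
        tol * (abs(newdev) + 0.1)) {
      dev <- newdev
      conv <- TRUE
      break
    }
    dev <- newdev
  }
  list(beta = beta, deviance = dev, converged = conv,
       mu = if (is.null(beta)) NULL else pmax(exp(eta), 1e-10))
}

nb_deviance <- function(y, mu, phi) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
  2 * sum(t1 - t2)
}

#' Moment-based dispersion estimation with median shrinkage
#'
#' Per-gene dispersions are estimated from design-adjusted residuals by a
#' leverage-corrected Pearson (pseudo-likelihood) moment equation: phi solves
#' `sum((y - mu)^2 / ((1 - h) * (mu + phi * mu^2))) = n`, where `mu` are
#' fitted means under the full design and `h` are hat-matrix leverages of the
#' weighted fit. With one sample per patient and condition the design absorbs
#' a large share of the residual degrees of freedom, so the leverage
#' correction is what keeps the estimator unbiased. Per-gene estimates are
#' shrunk toward a common dispersion obtained by pooling the estimating
#' equations across genes: `phi = (1 - w) * phi_gene + w * phi_common`.
#'
#' @param counts A `pdx_counts` (filtered).
#' @param condition,paired_by,ref_level Contrast specification as in
#'   [nb_test()]; determines the design used for mean removal.
#' @param norm Optional `tmm_factors`; computed if `NULL`.
#' @param shrink_weight Weight `w` on the common dispersion (default 0.5).
#' @return Named numeric vector of per-gene dispersions, floored at 1e-6,
#'   with the common dispersion in attribute `common`.
#' @export
estimate_dispersions <- function(counts, condition = "tissue",
                                 paired_by = NULL, ref_level = NULL,
                                 norm = NULL, shrink_weight = 0.5) {
  stopifnot(inherits(counts, "pdx_counts"))
  norm <- norm %||% tmm_factors(counts)
  des <- de_design(counts$meta, condition, ref_level, paired_by)
  X <- des$full
  n <- ncol(counts$counts)
  p <- ncol(X)
  if (n - p < 1) stop("no residual degrees of freedom in the design")
  offset <- log(norm$effective_lib)
  G <- nrow(counts$counts)
  r2_all <- mu_all <- matrix(NA_real_, G, n)
  phi_hat <- numeric(G)
  for (g in seq_len(G)) {
    y <- counts$counts[g, ]
    phi <- 1e-8  # start from the Poisson fit, then reweight until stable
    for (round in 1:6) {
      phi_prev <- phi
      fit <- nb_glm_fit(y, X, offset, phi)
      if (is.null(fit$mu)) break
      mu <- fit$mu
      w <- mu / (1 + phi * mu)
      h <- stats::hat(sqrt(w) * X, intercept = FALSE)
      r2 <- (y - mu)^2 / pmax(1 - h, 0.05)
      f <- function(ph) sum(r2 / (mu + ph * mu^2)) - n
      phi <- if (f(1e-8) <= 0) 0
        else if (f(100) >= 0) 100
        else stats::uniroot(f, c(1e-8, 100), tol = 1e-6)$root
      r2_all[g, ] <- r2
      mu_all[g, ] <- mu
      if (phi == 0 || abs(phi - phi_prev) < 1e-3 * (phi + 0.01)) break
    }
    phi_hat[g] <- if (is.finite(phi)) max(phi, 0) else 0
  }
  # common dispersion: pooled estimating equation across genes (averaging
  # the Pearson statistics before solving avoids the right skew of the
  # per-gene estimates)
  ok <- complete.cases(r2_all)
  fc <- function(ph) sum(r2_all[ok, ] / (mu_all[ok, ] + ph * mu_all[ok, ]^2)) -
    sum(ok) * n
  common <- if (fc(1e-8) <= 0) 0
    else if (fc(100) >= 0) 100
    else stats::uniroot(fc, c(1e-8, 100), tol = 1e-8)$root
  phi <- pmax((1 - shrink_weight) * phi_hat + shrink_weight * common, 1e-6)
  names(phi) <- rownames(counts$counts)
  attr(phi, "common") <- common
  phi
}

#' Negative-binomial likelihood-ratio test for a two-condition contrast
#'
#' Per gene, a negative-binomial log-linear model with offsets
#' `log(effective library size)` is fitted by iteratively reweighted least
#' squares; for a paired analysis the model contains patient indicator terms
#' plus the condition term, and the likelihood-ratio statistic compares the
#' full model against the patient-only model on one degree of freedom
#' (chi-squared). P-values are BH-adjusted. `paired_nb_test()` is the
#' patient-blocked front end used for donor-vs-PDX contrasts.
#'
#' @param counts A filtered `pdx_counts`.
#' @param condition Name of the two-level metadata column to test.
#' @param paired_by Metadata column defining blocks (e.g. `"patient_id"`);
#'   every block must contribute exactly one sample per condition. `NULL`
#'   gives the unpaired two-group test.
#' @param ref_level Reference (denominator) level of the condition.
#' @param dispersions Per-gene NB dispersions; estimated if `NULL`.
#' @param norm `tmm_factors`; computed if `NULL`.
#' @param alpha,lfc_threshold Significance thresholds used for the
#'   `significant` flag (FDR < alpha and |log2FC| > lfc_threshold).
#' @return data.frame of class `pdx_de`: gene_id, log2fc (clamped to +-20
#'   for display), pvalue, fdr, mean_cpm, significant, direction, converged.
#' @export
nb_test <- function(counts, condition = "tissue", paired_by = NULL,
                    ref_level = NULL, dispersions = NULL, norm = NULL,
                    alpha = 0.05, lfc_threshold = 1) {
  stopifnot(inherits(counts, "pdx_counts"))
  norm <- norm %||% tmm_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, condition, paired_by,
                                        ref_level, norm)
  des <- de_design(counts$meta, condition, ref_level, paired_by)
  offset <- log(norm$effective_lib)
  genes <- rownames(counts$counts)
  if (length(dispersions) == 1)
    dispersions <- rep_len(dispersions, length(genes))
  if (!is.null(names(dispersions))) dispersions <- dispersions[genes]
  if (any(is.na(dispersions) | dispersions <= 0))
    stop("dispersions must be positive and cover every gene")
  n_fail <- 0L
  res <- t(vapply(seq_along(genes), function(i) {
    y <- counts$counts[i, ]
    phi <- dispersions[[i]]
    full <- nb_glm_fit(y, des$full, offset, phi)
    red <- nb_glm_fit(y, des$reduced, offset, phi)
    if (is.null(full$beta) || is.null(red$beta) ||
        !is.finite(full$deviance) || !is.finite(red$deviance)) {
      n_fail <<- n_fail + 1L
      return(c(lfc = 0, p = 1, conv = 0))
    }
    stat <- max(red$deviance - full$deviance, 0)
    lfc <- full$beta[[ncol(des$full)]] / log(2)
    c(lfc = lfc, p = pchisq(stat, df = 1, lower.tail = FALSE),
      conv = as.numeric(full$converged && red$converged))
  }, numeric(3)))
  if (n_fail > 0)
    warning(n_fail, " gene(s) failed to converge; reported with p = 1")
  lfc <- pmin(pmax(res[, "lfc"], -20), 20)
  p <- res[, "p"]
  fdr <- benjamini_hochberg(p)
  out <- data.frame(
    gene_id = genes, log2fc = lfc, pvalue = p, fdr = fdr,
    mean_cpm = rowMeans(cpm(counts, lib = norm$effective_lib)),
    significant = fdr < alpha & abs(lfc) > lfc_threshold,
    direction = ifelse(lfc >= 0, "up", "down"),
    converged = res[, "conv"] == 1, stringsAsFactors = FALSE,
    row.names = NULL)
  class(out) <- c("pdx_de", "data.frame")
  out
}

#' @rdname nb_test
#' @param ... Passed on to [nb_test()].
#' @export
paired_nb_test <- function(counts, condition = "tissue",
                           paired_by = "patient_id", ...) {
  nb_test(counts, condition = condition, paired_by = paired_by, ...)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector in \[0,1\] (NA allowed; excluded and
#'   returned as NA).
#' @return Vector of BH-adjusted values (q-values) in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(out)
  o <- order(p, decreasing = TRUE)
  q <- pmin(cummin(p[o] * n / seq(n, 1)), 1)
  out[ok[o]] <- q
  out
}

#' Call differentially expressed genes
#'
#' Partitions significant genes (FDR < `alpha`, |log2FC| > `lfc`) by the sign
#' of the fold change.
#'
#' @param results A `pdx_de` data.frame.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @return List: `up`, `down` (gene_id vectors), `n_up`, `n_down`,
#'   `down_fraction`.
#' @export
call_degs <- function(results, alpha = 0.05, lfc = 1) {
  sig <- results$fdr < alpha & abs(results$log2fc) > lfc
  sig[is.na(sig)] <- FALSE
  up <- results$gene_id[sig & results$log2fc > 0]
  down <- results$gene_id[sig & results$log2fc < 0]
  n <- length(up) + length(down)
  list(up = up, down = down, n_up = length(up), n_down = length(down),
       down_fraction = if (n > 0) length(down) / n else NA_real_)
}
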