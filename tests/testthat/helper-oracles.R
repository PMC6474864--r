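# Independent oracles used across the suite. These deliberately share no code
# with the package: brute-force string handling, loops and closed forms only.

rc_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# every canonical k-mer of a sequence, one per position
oracle_canonical <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(n - k + 1)
  for (i in seq_len(n - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    r <- rc_str(km)
    out[i] <- if (km <= r) km else r
  }
  out
}

# brute-force BH: q_i = min over j with p_j >= p_i of min(1, n * p_j / rank_j)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- sapply(seq_len(n), function(j) {
      if (p[o[j]] >= p[i] - 1e-15) min(1, n * p[o[j]] / j) else Inf
    })
    q[i] <- min(cand)
  }
  q
}

# literal reimplementation of the TMM recipe, all loops
oracle_tmm <- function(m, lr_trim = 0.3, a_trim = 0.05) {
  lib <- colSums(m)
  uq <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) uq[s] <- quantile(m[, s] / lib[s], 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) {
    if (s == ref) { f[s] <- 1; next }
    Ms <- As <- ws <- c()
    for (g in seq_len(nrow(m))) {
      y <- m[g, s]; yr <- m[g, ref]
      if (y > 0 && yr > 0) {
        Ms <- c(Ms, log2((y / lib[s]) / (yr / lib[ref])))
        As <- c(As, 0.5 * log2((y / lib[s]) * (yr / lib[ref])))
        ws <- c(ws, (lib[s] - y) / (lib[s] * y) +
                  (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    keep <- Ms >= quantile(Ms, lr_trim) & Ms <= quantile(Ms, 1 - lr_trim) &
      As >= quantile(As, a_trim) & As <= quantile(As, 1 - a_trim)
    f[s] <- 2^(sum(Ms[keep] / ws[keep]) / sum(1 / ws[keep]))
  }
  f / exp(mean(log(f)))
}

# upper-tail hypergeometric by explicit enumeration of overlap sizes
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# package-independent null paired cohort (no condition effect)
null_paired_counts <- function(seed, n_genes = 1000, n_pairs = 9,
                               phi = 0.1, sigma = 0.3) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(50), 1)
  fac <- matrix(rlnorm(n_genes * n_pairs, -sigma^2 / 2, sigma), n_genes)
  mu <- cbind(base * fac, base * fac)
  y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), n_genes)
  rownames(y) <- sprintf("G%04d", seq_len(n_genes))
  meta <- data.frame(
    sample_id = c(sprintf("P%d_D", seq_len(n_pairs)),
                  sprintf("P%d_X", seq_len(n_pairs))),
    patient_id = rep(sprintf("P%d", seq_len(n_pairs)), 2),
    tissue = rep(c("donor", "pdx"), each = n_pairs),
    stringsAsFactors = FALSE)
  colnames(y) <- meta$sample_id
  count_matrix(y, meta)
}

toy_index <- function() {
  build_kmer_index(c(g1 = "ACGTA"), c(h1 = "TTTTT"), k = 3)
}
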