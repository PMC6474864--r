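test_that("CPM filter keeps exactly the genes the rule says", {
  lib <- rep(1e6, 18)
  m <- matrix(5L, 3, 18)
  m[2, ] <- 0L
  m[2, 1] <- 1L          # mean CPM 1/18 -> removed
  m[3, ] <- 2L           # mean CPM 2 -> retained (boundary)
  rownames(m) <- c("hi", "rare", "edge")
  colnames(m) <- sprintf("s%02d", 1:18)
  # pad library sizes to 1e6 with a filler gene
  m <- rbind(m, filler = as.integer(1e6 - colSums(m)))
  meta <- data.frame(sample_id = colnames(m),
                     tissue = rep(c("donor", "pdx"), 9))
  kept <- filter_low_expression(count_matrix(m, meta))
  expect_true(all(c("hi", "edge") %in% rownames(kept$counts)))
  expect_false("rare" %in% rownames(kept$counts))

  # random matrix vs brute-force recomputation of the rule
  set.seed(7)
  r <- matrix(rnbinom(500 * 18, mu = 8, size = 2), 500, 18,
              dimnames = list(sprintf("g%03d", 1:500), colnames(m)))
  cm <- count_matrix(r, meta)
  kept2 <- rownames(filter_low_expression(cm, 2)$counts)
  lib2 <- colSums(r)
  oracle <- rownames(r)[vapply(seq_len(nrow(r)), function(g) {
    mean(r[g, ] / lib2 * 1e6) >= 2
  }, logical(1))]
  expect_identical(kept2, oracle)
  expect_error(filter_low_expression(cm, 1e9), "all genes")
})

test_that("TMM factors match a literal reimplementation and its symmetries", {
  set.seed(19)
  m <- matrix(rnbinom(200 * 4, mu = exp(rnorm(200, 4, 1)), size = 5),
              200, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m[m < 0] <- 0
  tf <- tmm_factors(m)
  expect_equal(unname(tf$factors), oracle_tmm(m), tolerance = 1e-10)
  expect_equal(exp(mean(log(tf$factors))), 1, tolerance = 1e-12)

  # identical samples: all factors 1
  same <- matrix(rep(m[, 1], 4), ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(same)$factors), rep(1, 4))

  # doubling every count of one sample leaves M and A values unchanged; the
  # factor moves only through the depth-dependent precision weights
  m2 <- m
  m2[, 2] <- m2[, 2] * 2L
  expect_equal(tmm_factors(m2)$factors[2], tf$factors[2], tolerance = 0.01)

  zero <- m
  zero[, 3] <- 0L
  expect_error(tmm_factors(zero), "zero library")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(23)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- benjamini_hochberg(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_equal(q, oracle_bh(p))
  }
  # NA handling: missing p excluded, returned as NA
  q <- benjamini_hochberg(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(c(0.01, 0.5), "BH"))
  expect_error(benjamini_hochberg(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("dispersion estimation is calibrated for Poisson and NB data", {
  cm_pois <- null_paired_counts(101, n_genes = 400, phi = 1e-9)
  phi_p <- estimate_dispersions(cm_pois, paired_by = "patient_id")
  expect_lte(median(phi_p), 0.05)

  cm_nb <- null_paired_counts(102, n_genes = 400, phi = 0.1)
  phi_nb <- estimate_dispersions(cm_nb, paired_by = "patient_id")
  expect_gte(median(phi_nb), 0.05)
  expect_lte(median(phi_nb), 0.2)

  # single gene: the common (pooled) estimate is its own, so no shrinkage
  one <- cm_nb[1, ]
  phi_1 <- estimate_dispersions(one, paired_by = "patient_id")
  expect_length(phi_1, 1)
  expect_gte(phi_1[[1]], 1e-6)
  # pooling over one gene is that gene's own equation: shrinkage is a no-op
  expect_equal(phi_1[[1]], max(attr(phi_1, "common"), 1e-6),
               tolerance = 1e-4)
})

test_that("paired NB test: exact null gene, unpaired error, directionality", {
  cm <- null_paired_counts(31, n_genes = 50)
  # a gene with identical counts in donor and PDX of every pair
  m <- cm$counts
  m[1, 10:18] <- m[1, 1:9]
  m[, 10:18] <- m[, 1:9]   # make libraries equal too
  cm2 <- count_matrix(m, cm$meta)
  de <- paired_nb_test(cm2, ref_level = "donor",
                       dispersions = rep(0.1, 50))
  expect_equal(de$log2fc[1], 0, tolerance = 1e-6)
  expect_equal(de$pvalue[1], 1, tolerance = 1e-6)
  expect_true(all(de$direction[de$log2fc < 0] == "down"))

  bad_meta <- cm$meta
  bad_meta$patient_id[1] <- "P9"   # P1 loses its donor, P9 gets two
  expect_error(paired_nb_test(count_matrix(cm$counts, bad_meta),
                              ref_level = "donor"), "unpaired")
})

test_that("null simulations keep the false-positive rate near nominal", {
  for (s in c(301, 302)) {
    cm <- null_paired_counts(s, n_genes = 1000)
    de <- paired_nb_test(cm, ref_level = "donor")
    frac <- mean(de$pvalue < 0.05)
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.09)
    expect_lte(mean(de$fdr < 0.05), 0.01)
  }
})

test_that("a true -2 log2FC is recovered without material bias", {
  set.seed(57)
  n_genes <- 300
  base <- rlnorm(n_genes, log(80), 0.8)
  fac <- matrix(rlnorm(n_genes * 9, -0.045, 0.3), n_genes)
  lfc <- rep(0, n_genes)
  lfc[1:50] <- -2
  y <- matrix(rnbinom(n_genes * 18,
                      mu = cbind(base * fac, base * fac * 2^lfc), size = 10),
              n_genes)
  rownames(y) <- sprintf("g%03d", seq_len(n_genes))
  meta <- data.frame(sample_id = c(sprintf("P%d_D", 1:9),
                                   sprintf("P%d_X", 1:9)),
                     patient_id = rep(sprintf("P%d", 1:9), 2),
                     tissue = rep(c("donor", "pdx"), each = 9))
  colnames(y) <- meta$sample_id
  de <- paired_nb_test(count_matrix(y, meta), ref_level = "donor")
  est <- median(de$log2fc[1:50])
  expect_gte(est, -2.6)
  expect_lte(est, -1.4)
  degs <- call_degs(de)
  expect_gt(degs$n_down, 30)
})

test_that("pairing matters: breaking the blocks destroys power", {
  set.seed(61)
  n_genes <- 300
  base <- rlnorm(n_genes, log(80), 0.8)
  fac <- matrix(rlnorm(n_genes * 9, -0.32, 0.8), n_genes)  # strong pairing
  lfc <- rep(0, n_genes)
  lfc[1:60] <- -1.2
  y <- matrix(rnbinom(n_genes * 18,
                      mu = cbind(base * fac, base * fac * 2^lfc), size = 10),
              n_genes)
  rownames(y) <- sprintf("g%03d", seq_len(n_genes))
  meta <- data.frame(sample_id = c(sprintf("P%d_D", 1:9),
                                   sprintf("P%d_X", 1:9)),
                     patient_id = rep(sprintf("P%d", 1:9), 2),
                     tissue = rep(c("donor", "pdx"), each = 9))
  colnames(y) <- meta$sample_id
  cm <- count_matrix(y, meta)
  n_paired <- sum(call_degs(paired_nb_test(cm, ref_level = "donor"))$n_down)
  # permute patient labels within the PDX arm: pairs no longer match
  meta2 <- meta
  meta2$patient_id[10:18] <- meta$patient_id[c(13:18, 10:12)]
  cm2 <- count_matrix(y, meta2)
  n_broken <- sum(call_degs(nb_test(cm2, paired_by = "patient_id",
                                    ref_level = "donor"))$n_down)
  expect_gte(n_paired, 20)
  expect_lte(n_broken, 0.5 * n_paired)
})

test_that("rescaling one sample with its library leaves results stable", {
  cm <- null_paired_counts(71, n_genes = 300)
  de <- paired_nb_test(cm, ref_level = "donor")
  m2 <- cm$counts
  m2[, 3] <- m2[, 3] * 2L
  de2 <- paired_nb_test(count_matrix(m2, cm$meta), ref_level = "donor")
  # the NB likelihood is not exactly scale-equivariant, so equality is
  # approximate: fold changes move by far less than any calling threshold
  expect_lt(max(abs(de$log2fc - de2$log2fc)), 0.15)
  expect_gt(cor(de$pvalue, de2$pvalue), 0.99)
  expect_equal(call_degs(de)$down, call_degs(de2)$down)
})

test_that("fold changes and significance agree with edgeR on shared models", {
  cm <- null_paired_counts(81, n_genes = 150)
  m <- cm$counts
  m[1:20, 10:18] <- m[1:20, 10:18] * 4L   # strong induced effect
  cm <- count_matrix(m, cm$meta)
  phi <- estimate_dispersions(cm, paired_by = "patient_id")
  de <- paired_nb_test(cm, ref_level = "donor", dispersions = phi)

  suppressMessages(library(edgeR))
  y <- DGEList(counts = m)
  y <- calcNormFactors(y)
  block <- factor(cm$meta$patient_id)
  cond <- factor(cm$meta$tissue, levels = c("donor", "pdx"))
  design <- model.matrix(~ block + cond)
  fit <- glmFit(y, design, dispersion = unname(phi))
  lrt <- glmLRT(fit)
  expect_gt(cor(de$log2fc, lrt$table$logFC), 0.999)
  both_called <- intersect(call_degs(de)$up,
                           rownames(topTags(lrt, n = 25)$table))
  expect_gte(length(both_called), 15)
})
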