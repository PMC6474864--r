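test_that("index partitions canonical k-mers of the two references", {
  # identical references: everything shared
  same <- build_kmer_index(c(a = "ACGTACGT"), c(b = "ACGTACGT"), k = 5)
  expect_equal(same$info$n_graft_only, 0)
  expect_equal(same$info$n_host_only, 0)
  expect_gt(same$info$n_both, 0)

  # fully disjoint references: nothing shared
  disj <- build_kmer_index(c(a = "AAAAA"), c(b = "CCCCC"), k = 5)
  expect_equal(disj$info$n_both, 0)
  expect_equal(disj$info$n_graft_only, 1)
  expect_equal(disj$info$n_host_only, 1)

  # toy index vs exhaustive enumeration + canonicalization oracle
  idx <- toy_index()
  g_oracle <- unique(oracle_canonical("ACGTA", 3))
  h_oracle <- unique(oracle_canonical("TTTTT", 3))
  expect_setequal(pdxsep:::kmer_index_members(idx, "graft_only"),
                  setdiff(g_oracle, h_oracle))
  expect_setequal(pdxsep:::kmer_index_members(idx, "host_only"),
                  setdiff(h_oracle, g_oracle))
  expect_setequal(pdxsep:::kmer_index_members(idx, "both"),
                  intersect(g_oracle, h_oracle))

  # random references: partition matches the oracle and is disjoint
  set.seed(42)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  g <- c(x = mk(200), y = mk(150))
  h <- c(x = mk(180), y = substr(g[["x"]], 1, 90))
  ridx <- build_kmer_index(g, h, k = 7)
  go <- unique(unlist(lapply(g, oracle_canonical, k = 7)))
  ho <- unique(unlist(lapply(h, oracle_canonical, k = 7)))
  expect_setequal(pdxsep:::kmer_index_members(ridx, "graft_only"),
                  setdiff(go, ho))
  expect_setequal(pdxsep:::kmer_index_members(ridx, "host_only"),
                  setdiff(ho, go))
  expect_setequal(pdxsep:::kmer_index_members(ridx, "both"),
                  intersect(go, ho))

  expect_error(build_kmer_index(c(a = "ACGT"), c(b = "ACGT"), k = 4), "odd")
  expect_error(build_kmer_index(c(a = "ACG"), c(b = "ACGTT"), k = 5),
               "shortest")
})

test_that("read classification matches hand-enumerated k-mer memberships", {
  idx <- toy_index()
  cl <- classify_reads(c(r1 = "CGTA", r2 = "TTTT", r3 = "ACGTTT"), idx)
  expect_equal(as.character(cl$category), c("graft", "host", "ambiguous"))
  # CGTA: CGT and GTA both canonicalize into graft-only k-mers
  expect_equal(unlist(cl[1, c("h", "m", "b", "u")], use.names = FALSE),
               c(2L, 0L, 0L, 0L))
  # TTTT: two TTT positions, both host-only
  expect_equal(unlist(cl[2, c("h", "m", "b", "u")], use.names = FALSE),
               c(0L, 2L, 0L, 0L))
  # ACGTTT: ACG,CGT graft-only; GTT unknown; TTT host-only
  expect_equal(unlist(cl[3, c("h", "m", "b", "u")], use.names = FALSE),
               c(2L, 1L, 0L, 1L))

  # mates are pooled: one graft mate + one host mate = ambiguous
  clp <- classify_reads(list(read_id = "p1", r1 = "CGTA", r2 = "TTTT"), idx)
  expect_equal(as.character(clp$category), "ambiguous")

  # neither category and the short-mate error
  cln <- classify_reads(c(n1 = "GGTGG"), idx)
  expect_equal(as.character(cln$category), "neither")
  expect_error(classify_reads(c(tiny = "AC"), idx), "tiny")
})

test_that("categories partition reads and counts sum to k-mer positions", {
  gp <- simulate_gene_pairs(50, seed = 17)
  idx <- build_kmer_index(gp$graft_seq, gp$host_seq, 25)
  d <- cohort_design(n_pairs = 2, fragments_per_sample = 2000, seed = 17)
  hc <- simulate_counts(gp, d)
  rd <- simulate_reads(gp, d, hc, samples = "PH01_X")[[1]]
  cl <- classify_reads(rd, idx)
  npos <- 2 * (d$read_length - 25 + 1)
  expect_true(all(cl$h + cl$m + cl$b + cl$u == npos))
  expect_false(any(is.na(cl$category)))
  sel <- select_human(cl)
  expect_equal(sum(sel$tally), nrow(cl))
  expect_equal(length(sel$read_ids), sum(sel$tally[c("graft", "ambiguous",
                                                     "both")]))
})

test_that("selection keeps exactly graft, ambiguous and both", {
  cl <- data.frame(
    read_id = sprintf("r%d", 1:11),
    category = c(rep("graft", 3), rep("both", 2), "ambiguous",
                 rep("host", 4), "neither"))
  sel <- select_human(cl)
  expect_equal(length(sel$read_ids), 6)
  expect_equal(unname(sel$tally),
               c(3L, 4L, 2L, 1L, 1L))
  all_host <- data.frame(read_id = "a", category = "host")
  expect_equal(length(select_human(all_host)$read_ids), 0)
})

test_that("error-free graft reads are always retained (retention theorem)", {
  gp <- simulate_gene_pairs(100, seed = 23)
  idx <- build_kmer_index(gp$graft_seq, gp$host_seq, 25)
  d <- cohort_design(n_pairs = 2, fragments_per_sample = 4000,
                     base_error_rate = 0, seed = 23)
  hc <- simulate_counts(gp, d)
  for (s in c("PH01_P", "PH01_X")) {
    rd <- simulate_reads(gp, d, hc, samples = s)[[1]]
    graft <- rd$truth$true_species == "graft"
    cl <- classify_reads(rd, idx)
    expect_true(all(cl$m[graft] == 0))
    expect_true(all(cl$category[graft] %in% c("graft", "both")))
    sel <- select_human(cl)
    expect_true(all(sel$keep[graft]))
  }
})

test_that("host-read leakage decreases with divergence", {
  gp <- simulate_gene_pairs(400, conservation = function(n) runif(n, 0.5, 1),
                            seed = 29)
  idx <- build_kmer_index(gp$graft_seq, gp$host_seq, 25)
  set.seed(29)
  r1 <- r2 <- character(0)
  gene <- integer(0)
  per_gene <- 8
  for (i in seq_len(nrow(gp$genes))) {
    L <- gp$genes$length[i]
    st <- sample.int(L - 200 + 1, per_gene, TRUE)
    s <- gp$host_seq[i]
    r1 <- c(r1, substring(s, st, st + 50))
    r2 <- c(r2, vapply(substring(s, st + 149, st + 199), rc_str, ""))
    gene <- c(gene, rep(i, per_gene))
  }
  cl <- classify_reads(list(read_id = as.character(seq_along(r1)),
                            r1 = r1, r2 = unname(r2)), idx)
  ret <- cl$category %in% c("graft", "ambiguous", "both")
  bins <- cut(gp$genes$conservation[gene],
              c(0.5, 0.8, 0.9, 0.96, 1.0000001), right = FALSE)
  by_bin <- tapply(ret, bins, mean)
  expect_true(all(diff(by_bin) >= 0))
  expect_gt(by_bin[["[0.96,1)"]], 0.05)
  expect_equal(by_bin[["[0.5,0.8)"]], 0)
})

test_that("a serialized index reloads bit-identically", {
  gp <- simulate_gene_pairs(20, seed = 37, length_range = c(300L, 600L))
  idx <- build_kmer_index(gp$graft_seq, gp$host_seq, 15)
  f1 <- tempfile(fileext = ".idx")
  f2 <- tempfile(fileext = ".idx")
  save_kmer_index(idx, f1)
  idx2 <- load_kmer_index(f1)
  save_kmer_index(idx2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d <- cohort_design(n_pairs = 2, fragments_per_sample = 500, seed = 37)
  hc <- simulate_counts(gp, d)
  rd <- simulate_reads(gp, d, hc, samples = "PH01_X")[[1]]
  expect_identical(classify_reads(rd, idx)$category,
                   classify_reads(rd, idx2)$category)
  unlink(c(f1, f2))
})
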