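#' Cohort design for the dual-species simulator
#'
#' Captures the study conditions the simulator emulates: a cohort of matched
#' donor/PDX tumor pairs sequenced as short paired-end reads, with a stromal
#' compartment that is human in the donor tumor but replaced by mouse stroma
#' in the xenograft.
#'
#' @param n_pairs Number of donor/PDX pairs (patients). Default 9.
#' @param read_length Read length in nt for both mates. Default 51.
#' @param fragments_per_sample Number of sequenced fragments (read pairs) per
#'   sample. Default 2e5.
#' @param stroma_fraction_donor Fraction of donor-tumor fragments originating
#'   from the stromal compartment. The value 0.3 is a free parameter of the
#'   simulator (typical solid-tumor stromal content), not an estimate from any
#'   dataset.
#' @param mouse_stroma_fraction_pdx Target fraction of host (mouse) fragments
#'   in PDX samples. Default 0.16.
#' @param passages Integer vector of PDX passage numbers, one per pair
#'   (recycled). Default cycles 1..5.
#' @param fragment_length cDNA fragment length in nt; mates are read from the
#'   two fragment ends. Default 200.
#' @param base_error_rate Per-base iid substitution sequencing-error rate.
#'   Default 0.001.
#' @param patient_sigma Standard deviation (log scale) of the per-gene,
#'   per-patient lognormal expression factor shared by a donor/PDX pair.
#'   Default 0.3.
#' @param seed Integer seed; every simulation draw derives from it.
#' @return A list of class `pdx_design`.
#' @export
cohort_design <- function(n_pairs = 9L, read_length = 51L,
                          fragments_per_sample = 2e5,
                          stroma_fraction_donor = 0.3,
                          mouse_stroma_fraction_pdx = 0.16,
                          passages = NULL, fragment_length = 200L,
                          base_error_rate = 0.001, patient_sigma = 0.3,
                          seed = 1L) {
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  if (read_length <= 0) stop("read_length must be positive")
  fr <- c(stroma_fraction_donor, mouse_stroma_fraction_pdx, base_error_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (fragment_length < 2 * read_length)
    stop("fragment_length must be >= 2 * read_length")
  passages <- rep_len(if (is.null(passages)) 1:5 else as.integer(passages),
                      n_pairs)
  structure(list(
    n_pairs = as.integer(n_pairs), read_length = as.integer(read_length),
    fragments_per_sample = fragments_per_sample,
    stroma_fraction_donor = stroma_fraction_donor,
    mouse_stroma_fraction_pdx = mouse_stroma_fraction_pdx,
    passages = passages, fragment_length = as.integer(fragment_length),
    base_error_rate = base_error_rate, patient_sigma = patient_sigma,
    seed = as.integer(seed)), class = "pdx_design")
}

#' Simulate graft/host gene pairs with a conservation gradient
#'
#' Each gene carries a human (graft) transcript and a mouse (host) ortholog
#' derived from it by iid per-base substitution with probability
#' `1 - conservation`, substituting uniformly among the three other bases.
#' A seeded subset of genes is labeled `stroma`: expressed by human stroma in
#' donor tumors and by the mouse ortholog (only) in PDX tumors.
#'
#' @param n_genes Number of gene pairs (>= 10).
#' @param conservation Either a numeric vector of per-gene conservation values
#'   in \[0,1\], or a function `f(n)` drawing them. Default `rbeta(n, 17, 3)`
#'   (mean 0.85), spanning diverged to near-identical orthologs.
#' @param stroma_proportion Fraction of genes assigned to the stromal
#'   compartment (default 0.3).
#' @param length_range Transcript length range in nt (uniform draw).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters for the
#'   per-gene baseline expression weight.
#' @param dispersion Negative-binomial dispersion phi, scalar or per-gene.
#' @param sequences If `FALSE`, skip sequence synthesis (fast path for
#'   count-level simulations; `graft_seq`/`host_seq` are then empty).
#' @param seed Integer seed.
#' @return A list of class `pdx_gene_pairs` with elements `genes` (data.frame:
#'   gene_id, length, conservation, compartment, baseline_mean, dispersion),
#'   `graft_seq` and `host_seq` (named character vectors).
#' @export
simulate_gene_pairs <- function(n_genes, conservation = NULL,
                                stroma_proportion = 0.3,
                                length_range = c(500L, 3000L),
                                baseline_meanlog = log(30),
                                baseline_sdlog = 1,
                                dispersion = 0.1, sequences = TRUE,
                                seed = 1L) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  with_seed(seed, {
    cons <- if (is.null(conservation)) rbeta(n_genes, 17, 3)
      else if (is.function(conservation)) conservation(n_genes)
      else rep_len(conservation, n_genes)
    if (any(!is.finite(cons)) || any(cons < 0 | cons > 1))
      stop("conservation values must lie in [0, 1]")
    lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    phi <- rep_len(dispersion, n_genes)
    if (any(phi <= 0)) stop("dispersion must be positive")
    n_stroma <- floor(stroma_proportion * n_genes)
    compartment <- rep("tumor", n_genes)
    compartment[sample.int(n_genes, n_stroma)] <- "stroma"
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    bases <- c("A", "C", "G", "T")
    graft <- host <- character(n_genes)
    for (i in if (sequences) seq_len(n_genes) else integer(0)) {
      g <- sample.int(4L, lens[i], replace = TRUE)
      flip <- runif(lens[i]) < (1 - cons[i])
      h <- g
      if (any(flip)) {
        # shift by 1..3 mod 4: uniform over the three other bases
        h[flip] <- ((g[flip] - 1L + sample.int(3L, sum(flip),
                                               replace = TRUE)) %% 4L) + 1L
      }
      graft[i] <- paste(bases[g], collapse = "")
      host[i] <- paste(bases[h], collapse = "")
    }
    if (sequences) names(graft) <- names(host) <- gene_id
    structure(list(
      genes = data.frame(gene_id = gene_id, length = lens,
                         conservation = cons, compartment = compartment,
                         baseline_mean = baseline, dispersion = phi,
                         stringsAsFactors = FALSE),
      graft_seq = graft, host_seq = host), class = "pdx_gene_pairs")
  })
}

sample_ids_for <- function(design) {
  patient <- sprintf("PH%02d", seq_len(design$n_pairs))
  data.frame(
    sample_id = c(paste0(patient, "_P"), paste0(patient, "_X")),
    patient_id = c(patient, patient),
    tissue = rep(c("donor", "pdx"), each = design$n_pairs),
    passage = c(rep(NA_integer_, design$n_pairs), design$passages),
    stringsAsFactors = FALSE)
}

# Per-gene x per-patient lognormal factor (mean 1), shared by the donor and
# PDX sample of a pair: this is the correlation structure a paired design
# exploits, and what makes pairs cluster together.
patient_factors <- function(n_genes, design) {
  s <- design$patient_sigma
  matrix(rlnorm(n_genes * design$n_pairs, -s^2 / 2, s),
         nrow = n_genes, ncol = design$n_pairs)
}

#' Simulate ground-truth human (graft-origin) counts for a cohort
#'
#' Expected counts per sample combine the gene baseline, the compartment
#' weight (donor: tumor + stroma; PDX human fraction: tumor only -- the mouse
#' stroma expresses the host ortholog instead), and a per-gene lognormal
#' patient factor shared within each donor/PDX pair. Realized counts are
#' negative-binomial with the gene's dispersion. Expected totals are scaled so
#' a donor library has `fragments_per_sample` fragments with the design's
#' stromal read share, and a PDX human portion has
#' `(1 - mouse_stroma_fraction_pdx) * fragments_per_sample`.
#'
#' @param genes A `pdx_gene_pairs` object.
#' @param design A `pdx_design`.
#' @return A [count_matrix()] of ground-truth human-origin counts, with the
#'   patient factor matrix in attribute `patient_factors`.
#' @export
simulate_counts <- function(genes, design) {
  stopifnot(inherits(genes, "pdx_gene_pairs"), inherits(design, "pdx_design"))
  g <- genes$genes
  if (any(!is.finite(g$baseline_mean))) stop("baseline_mean must be finite")
  if (any(g$dispersion <= 0)) stop("dispersion must be positive")
  with_seed(design$seed, {
    n_genes <- nrow(g)
    fac <- patient_factors(n_genes, design)
    tum <- g$compartment != "stroma"
    str <- !tum
    sf <- design$stroma_fraction_donor
    msf <- design$mouse_stroma_fraction_pdx
    N <- design$fragments_per_sample
    meta <- sample_ids_for(design)
    mu <- matrix(0, n_genes, nrow(meta),
                 dimnames = list(g$gene_id, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      p <- match(meta$patient_id[j], sprintf("PH%02d", seq_len(design$n_pairs)))
      w <- g$baseline_mean * fac[, p]
      if (meta$tissue[j] == "donor") {
        mu[tum, j] <- (1 - sf) * N * w[tum] / sum(w[tum])
        mu[str, j] <- sf * N * w[str] / sum(w[str])
      } else {
        mu[tum, j] <- (1 - msf) * N * w[tum] / sum(w[tum])
      }
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / g$dispersion),
                     n_genes, ncol(mu), dimnames = dimnames(mu))
    out <- count_matrix(counts, meta)
    attr(out, "patient_factors") <- fac
    out
  })
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

apply_base_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  n_err <- rbinom(length(reads), rl, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(rl, n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

# Draw fragments from one transcript: uniform start, mates from the two ends
# in FR orientation. r2 is returned in transcript orientation; the caller
# reverse-complements whole samples at once.
fragments_from <- function(seq, n, design) {
  L <- nchar(seq)
  fl <- design$fragment_length
  rl <- design$read_length
  if (fl > L) stop("fragment_length exceeds transcript length ", L)
  start <- sample.int(L - fl + 1L, n, replace = TRUE)
  list(r1 = substring(seq, start, start + rl - 1L),
       r2 = substring(seq, start + fl - rl, start + fl - 1L))
}

#' Simulate paired-end reads for cohort samples
#'
#' Donor samples contain graft-origin fragments only (human tumor plus human
#' stroma). PDX samples mix graft-origin fragments (tumor compartment, taken
#' from `human_counts`) with host-origin fragments drawn from the host
#' orthologs of stromal genes so that the expected host read fraction equals
#' `mouse_stroma_fraction_pdx` (per-fragment binomial draw). Each returned
#' sample carries a truth table mapping read_id to true species and gene.
#'
#' @param genes A `pdx_gene_pairs` object.
#' @param design A `pdx_design`.
#' @param human_counts Ground-truth human counts from [simulate_counts()].
#' @param samples Character vector of sample_ids to generate (default: all).
#' @return Named list; per sample a list with `read_id`, `r1`, `r2` and
#'   `truth` (data.frame read_id, sample_id, true_species, true_gene).
#' @export
simulate_reads <- function(genes, design, human_counts, samples = NULL) {
  stopifnot(inherits(genes, "pdx_gene_pairs"), inherits(design, "pdx_design"))
  g <- genes$genes
  if (design$fragment_length > min(g$length))
    stop("fragment_length exceeds the shortest transcript")
  meta <- human_counts$meta
  fac <- attr(human_counts, "patient_factors")
  if (is.null(fac)) fac <- matrix(1, nrow(g), design$n_pairs)
  sel <- samples %||% meta$sample_id
  out <- vector("list", length(sel))
  names(out) <- sel
  str_idx <- which(g$compartment == "stroma")
  msf <- design$mouse_stroma_fraction_pdx
  for (s in sel) {
    j <- match(s, meta$sample_id)
    if (is.na(j)) stop("unknown sample ", s)
    # Per-sample seed derived from the design seed: generating one sample in
    # isolation reproduces its reads from a full-cohort run byte-for-byte.
    out[[s]] <- with_seed((design$seed * 1009L + j) %% .Machine$integer.max, {
      hc <- human_counts$counts[, j]
      gene_rep <- rep.int(seq_len(nrow(g)), hc)
      species <- rep.int("graft", length(gene_rep))
      if (meta$tissue[j] == "pdx" && msf > 0 && length(str_idx) > 0) {
        tot <- round(sum(hc) / (1 - msf))
        n_host <- rbinom(1, tot, msf)
        p <- match(meta$patient_id[j], sprintf("PH%02d",
                                               seq_len(design$n_pairs)))
        w <- g$baseline_mean[str_idx] * fac[str_idx, p]
        host_counts <- as.vector(stats::rmultinom(1, n_host, w / sum(w)))
        gene_rep <- c(gene_rep, rep.int(str_idx, host_counts))
        species <- c(species, rep.int("host", n_host))
      }
      n <- length(gene_rep)
      r1 <- r2 <- character(n)
      for (gi in unique(gene_rep)) {
        rows <- which(gene_rep == gi)
        for (sp in unique(species[rows])) {
          rr <- rows[species[rows] == sp]
          seqsrc <- if (sp == "graft") genes$graft_seq[gi]
                    else genes$host_seq[gi]
          fr <- fragments_from(seqsrc, length(rr), design)
          r1[rr] <- fr$r1
          r2[rr] <- fr$r2
        }
      }
      r2 <- revcomp_chr(r2)
      r1 <- apply_base_errors(r1, design$base_error_rate)
      r2 <- apply_base_errors(r2, design$base_error_rate)
      read_id <- sprintf("%s:%07d", s, seq_len(n))
      list(read_id = read_id, r1 = r1, r2 = r2, sample_id = s,
           truth = data.frame(read_id = read_id, sample_id = s,
                              true_species = species,
                              true_gene = g$gene_id[gene_rep],
                              stringsAsFactors = FALSE))
    })
  }
  out
}

#' Simulate a complete cohort (gene pairs, truth counts, sample sheet)
#'
#' Convenience wrapper tying [simulate_gene_pairs()] and [simulate_counts()]
#' together. Reads are generated on demand with [simulate_reads()] (they
#' dominate memory), so downstream pipeline drivers can stream one sample at
#' a time.
#'
#' @param design A `pdx_design`.
#' @param n_genes Number of gene pairs.
#' @param ... Passed to [simulate_gene_pairs()].
#' @return List of class `pdx_cohort`: `genes`, `design`, `human_counts`,
#'   `samples`.
#' @export
simulate_cohort <- function(design = cohort_design(), n_genes = 2000, ...) {
  genes <- simulate_gene_pairs(n_genes, seed = design$seed, ...)
  human_counts <- simulate_counts(genes, design)
  structure(list(genes = genes, design = design,
                 human_counts = human_counts,
                 samples = human_counts$meta), class = "pdx_cohort")
}

#' Write simulator outputs as plain-text files
#'
#' Writes `graft.fa`/`host.fa`, per-sample FASTQ (Phred+33, constant quality),
#' `truth_genes.tsv`, `counts_truth.tsv`, `samples.tsv` and per-sample
#' `truth_reads.tsv` into `dir`. Outputs are byte-identical across runs with
#' the same seed.
#'
#' @param cohort A `pdx_cohort`.
#' @param dir Output directory (created if absent).
#' @param reads Optional result of [simulate_reads()]; if `NULL`, no FASTQ is
#'   written.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, reads = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- Biostrings::DNAStringSet(cohort$genes$graft_seq)
  hs <- Biostrings::DNAStringSet(cohort$genes$host_seq)
  Biostrings::writeXStringSet(gs, file.path(dir, "graft.fa"))
  Biostrings::writeXStringSet(hs, file.path(dir, "host.fa"))
  tsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(cohort$genes$genes[, c("gene_id", "compartment", "conservation",
                             "baseline_mean")], "truth_genes.tsv")
  cm <- data.frame(gene_id = rownames(cohort$human_counts$counts),
                   cohort$human_counts$counts, check.names = FALSE)
  tsv(cm, "counts_truth.tsv")
  tsv(cohort$samples, "samples.tsv")
  for (s in names(reads %||% list())) {
    rd <- reads[[s]]
    q <- Biostrings::BStringSet(rep(paste(rep("I", nchar(rd$r1[1])),
                                          collapse = ""), length(rd$r1)))
    for (mate in 1:2) {
      x <- Biostrings::DNAStringSet(if (mate == 1) rd$r1 else rd$r2)
      names(x) <- rd$read_id
      Biostrings::writeXStringSet(
        x, file.path(dir, sprintf("%s_R%d.fastq", s, mate)),
        format = "fastq", qualities = q)
    }
    tsv(rd$truth, sprintf("%s_truth_reads.tsv", s))
  }
  invisible(dir)
}
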