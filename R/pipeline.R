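#' Patient pipeline: quantify all reads against the graft transcriptome
#'
#' The processing arm used for donor tumors: no graft/host classification,
#' every read pair is pseudo-aligned to the graft reference.
#'
#' @param reads Read list for one sample (see [simulate_reads()]).
#' @param gene_map A `gene_kmer_map` built from the graft transcripts.
#' @return As [count_sample()].
#' @export
run_patient_pipeline <- function(reads, gene_map) {
  count_sample(reads, gene_map)
}

#' PDX pipeline: classify, keep the human portion, then quantify
#'
#' The processing arm used for PDX tumors: reads are classified against the
#' two-species k-mer index, the human portion (graft / ambiguous / both) is
#' retained, and retained reads are pseudo-aligned to the graft reference.
#'
#' @param reads Read list for one sample.
#' @param index A `kmer_index`.
#' @param gene_map A `gene_kmer_map`.
#' @return List: `counts`, `n_assigned`, `n_unassigned`, `tally`
#'   (per-category read counts), `retained_fraction`.
#' @export
run_pdx_pipeline <- function(reads, index, gene_map) {
  cl <- classify_reads(reads, index)
  sel <- select_human(cl)
  kept <- list(read_id = reads$read_id[sel$keep], r1 = reads$r1[sel$keep],
               r2 = reads$r2[sel$keep])
  out <- count_sample(kept, gene_map)
  out$tally <- sel$tally
  out$retained_fraction <- sum(sel$keep) / max(1L, nrow(cl))
  out
}

#' Pipeline-sensitivity control on donor samples
#'
#' Processes the same donor samples through both the patient pipeline (all
#' reads quantified) and the PDX pipeline (classification-filtered), then
#' runs a paired NB test between the two processings of each sample. Any
#' significant gene is a technical artifact of read classification, to be
#' excluded from downstream donor-vs-PDX comparisons.
#'
#' @param donor_counts_patient,donor_counts_pdx Matrices of per-gene counts
#'   for the same donor samples through the two arms (columns in the same
#'   sample order).
#' @param alpha,lfc Thresholds for calling artifact genes.
#' @param min_avg_cpm Expression filter applied before testing.
#' @return List: `artifact_genes`, `de` (the `pdx_de` table), `n_tested`.
#' @export
pipeline_sensitivity_control <- function(donor_counts_patient,
                                         donor_counts_pdx,
                                         alpha = 0.05, lfc = 1,
                                         min_avg_cpm = 2) {
  stopifnot(identical(dim(donor_counts_patient), dim(donor_counts_pdx)))
  ids <- colnames(donor_counts_patient)
  meta <- data.frame(
    sample_id = c(paste0(ids, ".patient"), paste0(ids, ".pdx")),
    patient_id = c(ids, ids),
    pipeline = rep(c("patient", "pdx"), each = length(ids)),
    stringsAsFactors = FALSE)
  m <- cbind(donor_counts_patient, donor_counts_pdx)
  colnames(m) <- meta$sample_id
  cm <- filter_low_expression(count_matrix(m, meta), min_avg_cpm)
  de <- paired_nb_test(cm, condition = "pipeline", paired_by = "patient_id",
                       ref_level = "patient", alpha = alpha,
                       lfc_threshold = lfc)
  degs <- call_degs(de, alpha, lfc)
  list(artifact_genes = sort(c(degs$up, degs$down)), de = de,
       n_tested = nrow(de))
}

#' Simulate laser micro-dissected stroma / epithelium profiles
#'
#' Generates unpaired pure-compartment expression samples from the same gene
#' set as the cohort: stroma samples draw mostly from the stromal
#' compartment, epithelium samples mostly from the tumor compartment, with a
#' configurable cross-contamination fraction emulating imperfect dissection.
#' The resulting two-group DE list is the stand-in for an external
#' stroma-vs-carcinoma comparison.
#'
#' @param genes A `pdx_gene_pairs`.
#' @param n_per_group Samples per compartment (default 8).
#' @param depth Expected fragments per sample (default 1e5).
#' @param cross_contamination Fraction of a sample's expression drawn from
#'   the other compartment (default 0.1).
#' @param dispersion NB dispersion (default: per-gene values from `genes`).
#' @param seed Integer seed.
#' @return A `pdx_counts` with meta column `compartment` in
#'   `{stroma, epithelium}`.
#' @export
simulate_microdissected <- function(genes, n_per_group = 8, depth = 1e5,
                                    cross_contamination = 0.1,
                                    dispersion = NULL, seed = 1L) {
  g <- genes$genes
  phi <- dispersion %||% g$dispersion
  with_seed(seed, {
    str <- g$compartment == "stroma"
    norm_w <- function(x) if (sum(x) > 0) x / sum(x) else x
    w_str <- norm_w(ifelse(str, g$baseline_mean, 0))
    w_tum <- norm_w(ifelse(str, 0, g$baseline_mean))
    # an empty compartment contributes nothing (degenerate but valid input)
    prof_s <- (1 - cross_contamination) * w_str + cross_contamination * w_tum
    prof_e <- (1 - cross_contamination) * w_tum + cross_contamination * w_str
    prof_s <- norm_w(prof_s)
    prof_e <- norm_w(prof_e)
    n <- 2 * n_per_group
    mu <- cbind(matrix(prof_s * depth, nrow(g), n_per_group),
                matrix(prof_e * depth, nrow(g), n_per_group))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / phi, n)),
                     nrow(g), n)
    rownames(counts) <- g$gene_id
    meta <- data.frame(
      sample_id = c(sprintf("TS%02d", seq_len(n_per_group)),
                    sprintf("TE%02d", seq_len(n_per_group))),
      compartment = rep(c("stroma", "epithelium"), each = n_per_group),
      stringsAsFactors = FALSE)
    colnames(counts) <- meta$sample_id
    count_matrix(counts, meta)
  })
}

#' Run the full donor-vs-PDX workflow on a simulated cohort
#'
#' End-to-end orchestration of both study arms: (A) the pipeline-sensitivity
#' control (donor samples through patient and PDX pipelines, paired DE,
#' artifact gene list, conservation attribution) and (B) the donor-vs-PDX
#' XDG analysis with artifact genes excluded, followed by concordance
#' (pair correlations, dendrogram alignment, passage association) and overlap
#' enrichment against a simulated micro-dissected stroma/epithelium DE list.
#' Samples are streamed one at a time to bound memory.
#'
#' @param cohort A `pdx_cohort` from [simulate_cohort()].
#' @param k K-mer size for classification and pseudo-alignment (default 25).
#' @param alpha,lfc FDR and |log2FC| thresholds for DEG calling.
#' @param min_avg_cpm Mean-CPM expression filter (default 2). Applied before
#'   artifact-gene exclusion.
#' @param classify Set `FALSE` to disable classification in the control's
#'   PDX arm (both arms then see identical reads; a null control).
#' @param verbose Print progress.
#' @return List of class `pdx_workflow` with elements `counts`, `control`,
#'   `conservation_attribution`, `xdg`, `concordance`, `passage`,
#'   `enrichment`, `classification`, `manifest`.
#' @export
run_xdg_workflow <- function(cohort, k = 25L, alpha = 0.05, lfc = 1,
                             min_avg_cpm = 2, classify = TRUE,
                             verbose = FALSE) {
  stopifnot(inherits(cohort, "pdx_cohort"))
  genes <- cohort$genes
  design <- cohort$design
  say <- function(...) if (verbose) message(...)
  say("building k-mer index and gene map (k = ", k, ")")
  index <- build_kmer_index(genes$graft_seq, genes$host_seq, k)
  gene_map <- build_gene_kmer_map(genes$graft_seq, k)
  meta <- cohort$samples
  gid <- genes$genes$gene_id
  cohort_counts <- matrix(0L, length(gid), nrow(meta),
                          dimnames = list(gid, meta$sample_id))
  donor_ids <- meta$sample_id[meta$tissue == "donor"]
  ctrl_patient <- ctrl_pdx <- matrix(0L, length(gid), length(donor_ids),
                                     dimnames = list(gid, donor_ids))
  class_stats <- list()
  for (j in seq_len(nrow(meta))) {
    s <- meta$sample_id[j]
    say("processing ", s)
    reads <- simulate_reads(genes, design, cohort$human_counts,
                            samples = s)[[1]]
    assigned <- assign_reads(reads, gene_map)
    tab_all <- table(factor(assigned, levels = gid))
    if (meta$tissue[j] == "donor") {
      cohort_counts[, s] <- as.integer(tab_all)      # patient pipeline
      ctrl_patient[, s] <- as.integer(tab_all)
      keep <- if (classify)
        select_human(classify_reads(reads, index))$keep
      else rep(TRUE, length(assigned))
      ctrl_pdx[, s] <- as.integer(table(factor(assigned[keep],
                                               levels = gid)))
    } else {
      cl <- classify_reads(reads, index)
      sel <- select_human(cl)
      cohort_counts[, s] <- as.integer(table(factor(assigned[sel$keep],
                                                    levels = gid)))
      truth_host <- reads$truth$true_species == "host"
      class_stats[[s]] <- list(
        tally = sel$tally,
        retained_fraction = mean(sel$keep),
        true_host_fraction = mean(truth_host),
        host_reads_retained = sum(sel$keep & truth_host))
    }
  }

  say("pipeline-sensitivity control")
  control <- pipeline_sensitivity_control(ctrl_patient, ctrl_pdx,
                                          alpha, lfc, min_avg_cpm)
  cons_scores <- setNames(genes$genes$conservation, gid)
  attribution <- compare_flagged_vs_background(
    control$artifact_genes, control$de$gene_id, cons_scores)

  say("donor-vs-PDX differential expression")
  cm <- filter_low_expression(count_matrix(cohort_counts, meta), min_avg_cpm)
  # expression filter first, then artifact-gene exclusion
  tested <- setdiff(rownames(cm$counts), control$artifact_genes)
  n_before_exclusion <- nrow(cm$counts)
  cm_x <- cm[tested, ]
  de <- paired_nb_test(cm_x, condition = "tissue", paired_by = "patient_id",
                       ref_level = "donor", alpha = alpha,
                       lfc_threshold = lfc)
  xdg <- call_degs(de, alpha, lfc)
  xdg_genes <- c(xdg$up, xdg$down)

  say("concordance")
  log_expr <- cpm(cm_x, log = TRUE)
  pairs <- data.frame(donor = meta$sample_id[meta$tissue == "donor"],
                      pdx = meta$sample_id[meta$tissue == "pdx"],
                      stringsAsFactors = FALSE)
  conc <- list(
    before = pair_correlations(log_expr, pairs),
    after = pair_correlations(log_expr, pairs, exclude = xdg_genes),
    cluster_before = cluster_alignment(log_expr, pairs),
    cluster_after = cluster_alignment(log_expr, pairs,
                                      exclude = xdg_genes))
  pdx_cols <- meta$sample_id[meta$tissue == "pdx"]
  pdx_passages <- meta$passage[meta$tissue == "pdx"]
  pass <- if (length(unique(pdx_passages)) >= 4) {
    passage_association(log_expr[, pdx_cols, drop = FALSE], pdx_passages)
  } else {
    list(table = NULL, n_significant = NA_integer_, fdr_threshold = 0.30,
         note = "skipped: fewer than 4 distinct passage values")
  }

  say("stroma/epithelium overlap enrichment")
  micro <- simulate_microdissected(genes, seed = design$seed + 1L)
  micro_f <- filter_low_expression(micro, min_avg_cpm)
  micro_de <- nb_test(micro_f, condition = "compartment",
                      ref_level = "epithelium", alpha = alpha,
                      lfc_threshold = lfc)
  micro_degs <- call_degs(micro_de, alpha, lfc)
  universe <- intersect(de$gene_id, micro_de$gene_id)
  overlap <- hypergeom_overlap(intersect(xdg_genes, universe),
                               intersect(c(micro_degs$up, micro_degs$down),
                                         universe), universe)

  manifest <- list(
    package = "pdxsep",
    version = as.character(utils::packageVersion("pdxsep")),
    seed = design$seed, k = k, alpha = alpha, lfc = lfc,
    min_avg_cpm = min_avg_cpm,
    n_genes = length(gid), n_pairs = design$n_pairs,
    fragments_per_sample = design$fragments_per_sample,
    counts_checksum = sum(cohort_counts),
    n_artifact = length(control$artifact_genes),
    n_tested = nrow(de), n_before_exclusion = n_before_exclusion,
    n_xdg = xdg$n_up + xdg$n_down)

  structure(list(
    counts = count_matrix(cohort_counts, meta), filtered = cm,
    control = control, conservation_attribution = attribution,
    de = de, xdg = xdg, concordance = conc, passage = pass,
    enrichment = list(micro_de = micro_de, micro_degs = micro_degs,
                      overlap = overlap),
    classification = class_stats, index_info = index$info,
    manifest = manifest), class = "pdx_workflow")
}

#' Write a JSON run manifest
#'
#' @param workflow A `pdx_workflow`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(workflow, path) {
  jsonlite::write_json(workflow$manifest, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
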