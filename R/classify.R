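CATEGORY_LEVELS <- c("graft", "host", "both", "neither", "ambiguous")

#' Build a two-species k-mer classification index
#'
#' Canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) of the graft and host references are partitioned into three
#' pairwise-disjoint sets: graft-only, host-only, and shared ("both").
#' K-mers spanning a non-ACGT base are skipped and counted.
#'
#' @param graft,host Named character vectors of transcript sequences, paths to
#'   FASTA files, or `DNAStringSet`s.
#' @param k Odd k-mer size, `<= 31` and no longer than the reads to be
#'   classified. Default 25.
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(graft, host, k = 25L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  graft <- as_seq_chr(graft)
  host <- as_seq_chr(host)
  if (length(graft) == 0 || length(host) == 0)
    stop("both references must be non-empty")
  if (k > min(nchar(c(graft, host))))
    stop("k exceeds the shortest reference sequence")
  ptr <- .kmer_index_build(graft, host, k)
  info <- .kmer_index_info(ptr)
  if (info$skipped_graft + info$skipped_host > 0)
    message("skipped ", info$skipped_graft + info$skipped_host,
            " k-mers spanning non-ACGT bases")
  structure(list(ptr = ptr, k = k, info = info), class = "kmer_index")
}

as_seq_chr <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  x
}

#' @export
print.kmer_index <- function(x, ...) {
  i <- x$info
  cat(sprintf(
    "kmer_index (k = %d): %g graft-only, %g host-only, %g shared k-mers\n",
    x$k, i$n_graft_only, i$n_host_only, i$n_both))
  invisible(x)
}

#' Save / load a k-mer index as versioned sorted text
#'
#' The on-disk format is a header line (`pdxsep-kmer-index<TAB>v1<TAB>k=...`)
#' followed by sorted `kmer<TAB>category` lines, so identical indexes
#' serialize byte-identically.
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `save_kmer_index` returns `path` invisibly; `load_kmer_index`
#'   returns the reloaded `kmer_index`.
#' @export
save_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  .kmer_index_save(index$ptr, path)
  invisible(path)
}

#' @rdname save_kmer_index
#' @export
load_kmer_index <- function(path) {
  ptr <- .kmer_index_load(path)
  info <- .kmer_index_info(ptr)
  structure(list(ptr = ptr, k = info$k, info = info), class = "kmer_index")
}

# Sorted members of one partition, mostly for tests and inspection.
kmer_index_members <- function(index, set = c("graft_only", "host_only",
                                              "both")) {
  set <- match.arg(set)
  .kmer_index_members(index$ptr, match(set, c("graft_only", "host_only",
                                              "both")))
}

#' Classify paired-end reads as graft / host / both / neither / ambiguous
#'
#' For each read pair, every canonical k-mer position of both mates is looked
#' up in the index, giving counts `(h, m, b, u)` of k-mers found only in the
#' graft reference, only in the host reference, in both, or in neither. The
#' category is a pure function of those counts: `graft` if `h > 0 & m == 0`,
#' `host` if `m > 0 & h == 0`, `ambiguous` if `h > 0 & m > 0`, `both` if only
#' shared k-mers were seen, and `neither` if no k-mer matched.
#'
#' @param reads A list with `read_id`, `r1`, `r2` (as produced by
#'   [simulate_reads()]), or a character vector of mate-1 sequences.
#' @param index A `kmer_index`.
#' @param r2 Optional mate-2 sequences when `reads` is a character vector;
#'   `NULL` classifies single-end.
#' @return data.frame: read_id, h, m, b, u, category (factor).
#' @export
classify_reads <- function(reads, index, r2 = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.character(reads)) {
    reads <- list(read_id = names(reads) %||%
                    sprintf("read%d", seq_along(reads)),
                  r1 = unname(reads),
                  r2 = if (is.null(r2)) rep(NA_character_, length(reads))
                       else unname(r2))
  }
  short <- nchar(reads$r1) < index$k |
    (!is.na(reads$r2) & nchar(reads$r2) < index$k)
  if (any(short))
    stop("mate shorter than k for read(s): ",
         paste(head(reads$read_id[short], 5), collapse = ", "))
  cl <- .classify_reads(reads$r1, reads$r2, index$ptr)
  data.frame(read_id = reads$read_id, h = cl$h, m = cl$m, b = cl$b, u = cl$u,
             category = factor(CATEGORY_LEVELS[cl$category],
                               levels = CATEGORY_LEVELS),
             stringsAsFactors = FALSE)
}

#' Select the retained "human" portion of classified reads
#'
#' Reads classified as `graft`, `ambiguous` or `both` are retained as the
#' human portion; `host` and `neither` are excluded.
#'
#' @param classifications data.frame from [classify_reads()].
#' @return List: `read_ids` (retained), `tally` (per-category counts) and
#'   `fractions`.
#' @export
select_human <- function(classifications) {
  keep <- classifications$category %in% c("graft", "ambiguous", "both")
  tally <- table(factor(classifications$category, levels = CATEGORY_LEVELS))
  tally <- setNames(as.vector(tally, mode = "integer"), CATEGORY_LEVELS)
  list(read_ids = classifications$read_id[keep],
       keep = keep,
       tally = tally,
       fractions = tally / max(1L, nrow(classifications)))
}
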