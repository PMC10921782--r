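#' Build a k-mer transcript index
#'
#' Decomposes each transcript into canonical k-mers (the lexicographic
#' minimum of a k-mer and its reverse complement, so the index is
#' strand-agnostic) and interns, per k-mer, the equivalence class of
#' transcripts containing it. Transcripts shorter than k are skipped with a
#' warning.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param k k-mer length, 1--31. Default 31, the de facto standard for
#'   transcriptome pseudoalignment.
#' @param transcript_to_gene optional named character vector mapping
#'   transcript names to gene ids; default strips a trailing `.N` isoform
#'   suffix.
#' @return an object of class `transcript_index`.
#' @export
build_index <- function(transcripts, k = 31L,
                        transcript_to_gene = NULL) {
  stopifnot(length(transcripts) > 0, !is.null(names(transcripts)))
  if (anyDuplicated(names(transcripts)))
    stop("duplicate transcript ids in index input")
  if (is.null(transcript_to_gene)) {
    transcript_to_gene <- setNames(sub("\\.[0-9]+$", "", names(transcripts)),
                                   names(transcripts))
  }
  if (!all(names(transcripts) %in% names(transcript_to_gene)))
    stop("transcript_to_gene does not cover all transcripts")
  built <- .px_build_index(unname(toupper(transcripts)), as.integer(k))
  if (any(built$skipped))
    warning(sum(built$skipped), " transcript(s) shorter than k = ", k,
            " contribute no k-mers")
  structure(list(ptr = built$ptr, k = as.integer(k),
                 tx_names = names(transcripts),
                 tx_len = nchar(unname(transcripts)),
                 genes = unname(transcript_to_gene[names(transcripts)]),
                 n_kmers = built$n_kmers, n_ecs = built$n_ecs),
            class = "transcript_index")
}

#' @export
print.transcript_index <- function(x, ...) {
  cat("transcript_index: ", length(x$tx_names), " transcripts, k = ", x$k,
      ", ", format(x$n_kmers, big.mark = ","), " k-mers in ",
      x$n_ecs, " equivalence classes\n", sep = "")
  invisible(x)
}

#' Persist / restore a transcript index
#'
#' Single binary artifact with a version header.
#'
#' @param index a `transcript_index`.
#' @param path file path.
#' @return `read_index()`: a `transcript_index`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "transcript_index"))
  .px_save_index(index$ptr, path, index$tx_names, index$genes)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- .px_load_index(path)
  structure(list(ptr = x$ptr, k = x$k, tx_names = x$tx_names,
                 tx_len = x$tx_len, genes = x$genes,
                 n_kmers = .px_index_info(x$ptr)$n_kmers,
                 n_ecs = .px_index_info(x$ptr)$n_ecs),
            class = "transcript_index")
}

#' Number of index k-mers unique to each transcript
#'
#' Transcripts are pairwise k-mer-distinguishable when every transcript
#' carries at least one k-mer found in no other transcript.
#'
#' @param index a `transcript_index`.
#' @return named numeric vector of unique-k-mer counts per transcript.
#' @export
unique_kmer_counts <- function(index) {
  stopifnot(inherits(index, "transcript_index"))
  setNames(.px_unique_kmers(index$ptr), index$tx_names)
}

#' Pseudoalign read pairs to a transcript index
#'
#' A mate's compatibility set is the intersection of its k-mers'
#' transcript equivalence classes; the pair's set is the intersection of the
#' two mate sets. Under the default `missing_kmers = "strict"` semantics a
#' k-mer absent from the index empties its mate's set, so a mate is
#' compatible with a transcript only if the transcript contains the mate
#' exactly (in either orientation) -- identical-match compatibility. With
#' `missing_kmers = "skip"`, absent k-mers are ignored instead, salvaging
#' partially divergent reads as some pseudoaligners do. In both modes a
#' mate with no indexed k-mers at all, or an empty intersection, leaves the
#' pair unassigned.
#'
#' @param index a [build_index()] result.
#' @param pairs a `read_pairs` object, or a list with `mate1` and `mate2`
#'   character vectors.
#' @param missing_kmers `"strict"` (default) or `"skip"`; see Details.
#' @return an object of class `pseudoalignments`: a list with
#'   `assignment` (per pair, index into `sets`; 0 = unassigned) and `sets`
#'   (list of character vectors of compatible transcript ids).
#' @export
pseudoalign <- function(index, pairs,
                        missing_kmers = c("strict", "skip")) {
  stopifnot(inherits(index, "transcript_index"))
  missing_kmers <- match.arg(missing_kmers)
  res <- .px_align(index$ptr, pairs$mate1, pairs$mate2,
                   missing_kmers == "strict")
  sets <- lapply(res$sets, function(ix) index$tx_names[ix])
  structure(list(assignment = res$assignment, sets = sets,
                 n_pairs = length(res$assignment),
                 n_assigned = sum(res$assignment > 0L),
                 missing_kmers = missing_kmers),
            class = "pseudoalignments")
}

#' Pseudoalign a single read pair
#'
#' @inheritParams pseudoalign
#' @param mate1,mate2 single mate sequences.
#' @return character vector of compatible transcript ids (empty if
#'   unassigned).
#' @export
pseudoalign_pair <- function(index, mate1, mate2,
                             missing_kmers = c("strict", "skip")) {
  al <- pseudoalign(index, list(mate1 = mate1, mate2 = mate2),
                    missing_kmers)
  if (al$assignment[1] == 0L) character() else al$sets[[al$assignment[1]]]
}

#' @export
print.pseudoalignments <- function(x, ...) {
  cat("pseudoalignments:", x$n_assigned, "of", x$n_pairs,
      "pairs assigned (", length(x$sets), "distinct compatibility sets)\n")
  invisible(x)
}

#' Quantify transcripts from pseudoaligned read pairs
#'
#' Each assigned pair contributes 1/|S| to every transcript of its
#' compatibility set S (even splitting). Unassigned pairs are tallied.
#'
#' @inheritParams pseudoalign
#' @param alignments optionally, a precomputed [pseudoalign()] result for
#'   these pairs.
#' @return an object of class `quant_table`: a data frame with columns
#'   `transcript_id`, `length`, `est_count`, `tpm`, with attributes
#'   `assigned` and `unassigned` (pair totals).
#' @export
quantify <- function(index, pairs,
                     missing_kmers = c("strict", "skip"),
                     alignments = NULL) {
  stopifnot(inherits(index, "transcript_index"))
  if (is.null(alignments))
    alignments <- pseudoalign(index, pairs, missing_kmers)
  counts <- numeric(length(index$tx_names))
  names(counts) <- index$tx_names
  if (length(alignments$sets)) {
    per_set <- tabulate(alignments$assignment[alignments$assignment > 0L],
                        nbins = length(alignments$sets))
    for (j in seq_along(alignments$sets)) {
      s <- alignments$sets[[j]]
      counts[s] <- counts[s] + per_set[j] / length(s)
    }
  }
  out <- data.frame(transcript_id = index$tx_names,
                    length = index$tx_len,
                    est_count = unname(counts),
                    stringsAsFactors = FALSE)
  out$tpm <- compute_tpm(out$est_count, out$length)
  attr(out, "assigned") <- alignments$n_assigned
  attr(out, "unassigned") <- alignments$n_pairs - alignments$n_assigned
  class(out) <- c("quant_table", "data.frame")
  out
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table:", nrow(x), "transcripts;",
      format(attr(x, "assigned")), "pairs assigned,",
      format(attr(x, "unassigned")), "unassigned\n")
  NextMethod()
}

#' Transcripts-per-million from counts and lengths
#'
#' `tpm_t = 1e6 * (c_t / l_t) / sum_u (c_u / l_u)`; all-zero counts give
#' all-zero TPMs. Plain transcript length is used (no effective-length
#' correction), the honest choice for fixed-insert error-free simulation;
#' this differs from tools that model fragment-length distributions.
#'
#' @param counts non-negative numeric vector of counts.
#' @param lengths positive numeric vector of transcript lengths.
#' @return numeric vector of TPMs summing to 1e6 (or all 0).
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) return(rep(0, length(counts)))
  1e6 * rate / tot
}

#' Aggregate transcript-level quantification to genes
#'
#' Gene value = sum over the gene's transcripts, for both counts and TPMs.
#'
#' @param quant a `quant_table`.
#' @param transcript_to_gene optional named map transcript -> gene; defaults
#'   to the mapping recorded in the table's originating index (a trailing
#'   `.N` suffix strip if absent).
#' @return data frame `gene_id`, `est_count`, `tpm` of class `gene_quant`.
#' @export
aggregate_to_gene <- function(quant, transcript_to_gene = NULL) {
  if (is.null(transcript_to_gene))
    transcript_to_gene <- setNames(sub("\\.[0-9]+$", "", quant$transcript_id),
                                   quant$transcript_id)
  gene <- unname(transcript_to_gene[quant$transcript_id])
  if (anyNA(gene))
    stop("transcript(s) without a gene mapping: ",
         paste(utils::head(quant$transcript_id[is.na(gene)], 3), collapse = ", "))
  cnt <- rowsum(quant$est_count, gene)
  tpm <- rowsum(quant$tpm, gene)
  out <- data.frame(gene_id = rownames(cnt), est_count = cnt[, 1],
                    tpm = tpm[, 1], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "assigned") <- attr(quant, "assigned")
  attr(out, "unassigned") <- attr(quant, "unassigned")
  class(out) <- c("gene_quant", "data.frame")
  out
}
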