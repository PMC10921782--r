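#' Build a pantranscriptome reference
#'
#' Pools the reference cultivar's transcripts with every cultivar transcript
#' whose gene is in a strict 1-to-1 orthology relationship with a reference
#' gene. Transcript ids are namespaced `cultivar|transcript` so annotations
#' that reuse ids cannot collide, and every pan transcript carries the
#' reference gene it will be collapsed onto.
#'
#' @param reference_transcripts named character vector of reference
#'   transcripts.
#' @param cultivar_transcripts named list (by cultivar) of named character
#'   vectors of transcripts.
#' @param orthology data frame with columns `cultivar`, `cultivar_gene`,
#'   `reference_gene`, `relationship`; only `one_to_one` rows are used.
#' @param reference_name name of the reference cultivar for namespacing.
#' @param transcript_to_gene optional transcript -> gene map; default strips
#'   a trailing `.N` suffix.
#' @return an object of class `pan_reference`: a list with `seqs` (named
#'   character vector of all included transcripts) and `map` (data frame
#'   `pan_transcript_id`, `cultivar`, `transcript_id`, `reference_gene`),
#'   plus inclusion counts per cultivar.
#' @export
build_pantranscriptome <- function(reference_transcripts,
                                   cultivar_transcripts = list(),
                                   orthology = NULL,
                                   reference_name = "ref",
                                   transcript_to_gene = NULL) {
  stopifnot(!is.null(names(reference_transcripts)))
  t2g <- function(tx) {
    if (is.null(transcript_to_gene)) sub("\\.[0-9]+$", "", tx)
    else unname(transcript_to_gene[tx])
  }
  ref_map <- data.frame(pan_transcript_id =
                          paste0(reference_name, "|",
                                 names(reference_transcripts)),
                        cultivar = reference_name,
                        transcript_id = names(reference_transcripts),
                        reference_gene = t2g(names(reference_transcripts)),
                        stringsAsFactors = FALSE)
  seqs <- setNames(unname(reference_transcripts), ref_map$pan_transcript_id)
  maps <- list(ref_map)
  included <- setNames(length(reference_transcripts), reference_name)
  excluded <- setNames(0L, reference_name)
  for (cv in names(cultivar_transcripts)) {
    tx <- cultivar_transcripts[[cv]]
    stopifnot(!is.null(names(tx)))
    orth <- orthology[orthology$cultivar == cv &
                        orthology$relationship == "one_to_one", ,
                      drop = FALSE]
    if (anyDuplicated(orth$cultivar_gene) ||
        anyDuplicated(orth$reference_gene))
      stop("orthology for '", cv, "' is not 1-to-1")
    genes <- t2g(names(tx))
    unknown <- setdiff(orth$cultivar_gene, genes)
    if (length(unknown))
      stop("orthology for '", cv, "' references unknown gene(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
    keep <- genes %in% orth$cultivar_gene
    included[cv] <- sum(keep)
    excluded[cv] <- sum(!keep)
    if (any(keep)) {
      m <- data.frame(pan_transcript_id = paste0(cv, "|", names(tx)[keep]),
                      cultivar = cv,
                      transcript_id = names(tx)[keep],
                      reference_gene = orth$reference_gene[
                        match(genes[keep], orth$cultivar_gene)],
                      stringsAsFactors = FALSE)
      seqs <- c(seqs, setNames(unname(tx[keep]), m$pan_transcript_id))
      maps[[length(maps) + 1]] <- m
    }
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  structure(list(seqs = seqs, map = map, included = included,
                 excluded = excluded, reference_name = reference_name),
            class = "pan_reference")
}

#' @export
print.pan_reference <- function(x, ...) {
  cat("pan_reference:", length(x$seqs), "transcripts over",
      length(unique(x$map$reference_gene)), "reference genes\n")
  inc <- paste0(names(x$included), "=", x$included, collapse = ", ")
  cat("  included per cultivar:", inc, "\n")
  invisible(x)
}

#' Recover cultivar and original transcript id from pan ids
#'
#' @param pan_ids character vector of `cultivar|transcript` ids.
#' @return data frame `cultivar`, `transcript_id`.
#' @export
split_pan_id <- function(pan_ids) {
  m <- regmatches(pan_ids, regexpr("|", pan_ids, fixed = TRUE),
                  invert = TRUE)
  data.frame(cultivar = vapply(m, `[`, "", 1),
             transcript_id = vapply(m, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Sum pantranscriptome quantification onto reference genes
#'
#' For each reference gene, counts (and TPMs) are summed over the gene's own
#' transcripts and all 1-to-1 orthologous cultivar transcripts, collapsing a
#' pan-reference quantification onto the reference annotation. TPMs are
#' summed exactly as counts are, without renormalisation (set
#' `renormalize_tpm = TRUE` to rescale the summed TPMs back to 1e6).
#'
#' @param quant a `quant_table` over the pan reference's transcripts.
#' @param pan a [build_pantranscriptome()] result.
#' @param renormalize_tpm rescale summed TPMs to total 1e6 (default FALSE).
#' @return data frame `gene_id`, `est_count`, `tpm` of class `gene_quant`,
#'   one row per reference gene.
#' @export
sum_orthologue_counts <- function(quant, pan, renormalize_tpm = FALSE) {
  stopifnot(inherits(pan, "pan_reference"))
  if (!setequal(quant$transcript_id, pan$map$pan_transcript_id))
    stop("quantification does not cover exactly the pan reference's transcripts")
  ref_gene <- pan$map$reference_gene[match(quant$transcript_id,
                                           pan$map$pan_transcript_id)]
  if (anyNA(ref_gene))
    stop("transcript(s) without a reference-gene mapping")
  cnt <- rowsum(quant$est_count, ref_gene)
  tpm <- rowsum(quant$tpm, ref_gene)
  out <- data.frame(gene_id = rownames(cnt), est_count = cnt[, 1],
                    tpm = tpm[, 1], stringsAsFactors = FALSE)
  if (renormalize_tpm && sum(out$tpm) > 0)
    out$tpm <- 1e6 * out$tpm / sum(out$tpm)
  rownames(out) <- NULL
  attr(out, "assigned") <- attr(quant, "assigned")
  attr(out, "unassigned") <- attr(quant, "unassigned")
  class(out) <- c("gene_quant", "data.frame")
  out
}

#' Write a pan reference to disk
#'
#' FASTA of namespaced transcripts plus the mapping TSV
#' (`pan_transcript_id`, `cultivar`, `transcript_id`, `reference_gene`).
#'
#' @param pan a `pan_reference`.
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
write_pantranscriptome <- function(pan, prefix) {
  stopifnot(inherits(pan, "pan_reference"))
  p1 <- paste0(prefix, ".fasta")
  write_fasta(pan$seqs, p1)
  p2 <- paste0(prefix, ".map.tsv")
  write_tsv(pan$map, p2)
  invisible(c(p1, p2))
}
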