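#' Classify per-gene quantification accuracy
#'
#' With 1000 simulated pairs per gene, a gene is correctly quantified when
#' its estimated count lies in `[lower, upper]` (bounds inclusive),
#' underestimated below `lower` and overestimated above `upper`.
#'
#' @param gene_counts named numeric vector, or a `gene_quant` data frame.
#' @param lower,upper classification bounds (defaults 500 and 1500).
#' @return data frame `gene_id`, `est_count`, `class` of class
#'   `gene_bias_class`; `class` is a factor with levels `underestimated`,
#'   `correct`, `overestimated`.
#' @export
classify_quantification <- function(gene_counts, lower = 500,
                                    upper = 1500) {
  if (is.data.frame(gene_counts))
    gene_counts <- setNames(gene_counts$est_count, gene_counts$gene_id)
  stopifnot(all(gene_counts >= 0), lower <= upper)
  cls <- ifelse(gene_counts < lower, "underestimated",
                ifelse(gene_counts > upper, "overestimated", "correct"))
  out <- data.frame(gene_id = names(gene_counts),
                    est_count = unname(gene_counts),
                    class = factor(cls, levels = c("underestimated",
                                                   "correct",
                                                   "overestimated")),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_bias_class", "data.frame")
  out
}

#' @method summary gene_bias_class
#' @export
summary.gene_bias_class <- function(object, ...) {
  tab <- table(object$class)
  pct <- 100 * as.numeric(tab) / nrow(object)
  data.frame(class = names(tab), n = as.numeric(tab), percent = pct)
}

#' Gene set eligible for a self- or cross-mapping comparison
#'
#' Self-mapping uses every gene from which reads were simulated.
#' Cross-mapping restricts to genes simulated in the read-source cultivar
#' that are in a 1-to-1 relationship with a reference gene from which reads
#' were also simulated; the returned ids are reference gene ids.
#'
#' @param simulated_ref character vector of reference genes with simulated
#'   reads.
#' @param simulated_cultivar character vector of cultivar genes with
#'   simulated reads (ignored for self-mapping).
#' @param orthology orthology data frame (see [generate_pangenome()]);
#'   ignored for self-mapping.
#' @param cultivar cultivar name, or `NULL` for self-mapping mode.
#' @return character vector of eligible reference gene ids.
#' @export
cross_mapping_gene_set <- function(simulated_ref,
                                   simulated_cultivar = NULL,
                                   orthology = NULL, cultivar = NULL) {
  if (is.null(cultivar)) return(simulated_ref)
  orth <- orthology[orthology$cultivar == cultivar &
                      orthology$relationship == "one_to_one", ,
                    drop = FALSE]
  keep <- orth$cultivar_gene %in% simulated_cultivar &
    orth$reference_gene %in% simulated_ref
  orth$reference_gene[keep]
}

#' Compare gene counts between two cultivars mapped to a common reference
#'
#' An orthologue pair is incorrectly quantified when the ratio of its two
#' counts falls outside `[1/fold, fold]`. A zero in one cultivar with a
#' positive count in the other is incorrect; a double zero is correct.
#'
#' @param counts_x,counts_y named numeric vectors of gene counts for the
#'   two cultivars (reference gene ids).
#' @param pairs character vector of gene ids to compare (1-to-1 orthologues
#'   quantified in both runs); default the intersection of the two names.
#' @param fold fold-change threshold (default 1.5).
#' @return data frame `gene_id`, `count_x`, `count_y`, `incorrect`,
#'   `lower` (which cultivar is lower: `"x"`, `"y"` or `NA`).
#' @export
compare_cultivars <- function(counts_x, counts_y, pairs = NULL,
                              fold = 1.5) {
  stopifnot(fold > 1)
  if (is.null(pairs)) pairs <- intersect(names(counts_x), names(counts_y))
  x <- unname(counts_x[pairs])
  y <- unname(counts_y[pairs])
  ratio <- ifelse(y == 0, ifelse(x == 0, 1, Inf), x / y)
  incorrect <- ratio > fold | ratio < 1 / fold
  lower <- ifelse(!incorrect, NA_character_,
                  ifelse(x < y, "x", "y"))
  out <- data.frame(gene_id = pairs, count_x = x, count_y = y,
                    incorrect = incorrect, lower = lower,
                    stringsAsFactors = FALSE)
  class(out) <- c("cultivar_comparison", "data.frame")
  out
}

#' Windowed bias score from per-gene classifications
#'
#' Tiles each chromosome into fixed windows (0-based half-open; genes are
#' assigned to the window containing their start coordinate) and scores each
#' window as `(-1) * n_underestimated + (+1) * n_overestimated`, so runs of
#' underestimated genes -- the signature of an introgression under
#' single-reference mapping -- show up as strongly negative windows.
#'
#' @param classes a [classify_quantification()] result.
#' @param gene_coords data frame `gene_id`, `chrom`, `start` (and
#'   optionally `end`) in reference coordinates.
#' @param window_size window width in bp (field standard 5 Mbp; use smaller
#'   windows for scaled-down genomes).
#' @param chrom_lengths optional named vector; defaults to the maximum gene
#'   end/start per chromosome.
#' @return data frame `chrom`, `start`, `end`, `n_under`, `n_over`,
#'   `score` of class `window_score_track`.
#' @export
window_bias_score <- function(classes, gene_coords, window_size = 5e6,
                              chrom_lengths = NULL) {
  stopifnot(window_size > 0)
  g <- merge(as.data.frame(classes), gene_coords, by = "gene_id")
  if (nrow(g) < nrow(classes))
    stop("gene(s) without coordinates: ",
         paste(utils::head(setdiff(classes$gene_id, gene_coords$gene_id), 3),
               collapse = ", "))
  if (is.null(chrom_lengths)) {
    top <- if ("end" %in% names(g)) g$end else g$start + 1
    chrom_lengths <- tapply(top, g$chrom, max)
  }
  win <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    s <- seq(0, max(chrom_lengths[[ch]] - 1, 0), by = window_size)
    data.frame(chrom = ch, start = s,
               end = pmin(s + window_size, chrom_lengths[[ch]]))
  }))
  g$win <- paste0(g$chrom, ":", floor(g$start / window_size))
  key <- paste0(win$chrom, ":", win$start / window_size)
  bad <- !(g$win %in% key)
  if (any(bad)) stop("gene outside any window: ", g$gene_id[bad][1])
  win$n_under <- as.numeric(table(factor(g$win[g$class == "underestimated"],
                                         levels = key)))
  win$n_over <- as.numeric(table(factor(g$win[g$class == "overestimated"],
                                        levels = key)))
  win$score <- -win$n_under + win$n_over
  class(win) <- c("window_score_track", "data.frame")
  win
}

#' Percent identity of two coding sequences by global alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1, gap
#' open -2, gap extend -1; identity is matches over alignment length
#' (including gap columns) times 100. Symmetric in its arguments. With
#' full-length, indel-free orthologue pairs this agrees with the identity of
#' a best local (blast-style) hit.
#'
#' @param seq_a,seq_b nucleotide sequences (IUPAC letters).
#' @return percent identity in `[0, 100]`.
#' @export
cds_identity <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  iupac <- "^[ACGTRYSWKMBDHVN]+$"
  if (!grepl(iupac, seq_a) || !grepl(iupac, seq_b))
    stop("sequences must contain IUPAC nucleotide letters only")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 2, gapExtension = 1)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Bin orthologue identities into genomic windows
#'
#' @param identities named numeric vector of percent identities (reference
#'   gene ids).
#' @param gene_coords data frame `gene_id`, `chrom`, `start` (reference
#'   coordinates).
#' @param window_size window width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data frame `chrom`, `start`, `end`, `mean_identity`, `n`; empty
#'   windows carry `n = 0` and `NA` identity.
#' @export
bin_identity <- function(identities, gene_coords, window_size = 5e6,
                         chrom_lengths = NULL) {
  stopifnot(window_size > 0)
  if (length(identities) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_identity = numeric(),
                      n = integer()))
  }
  g <- gene_coords[match(names(identities), gene_coords$gene_id), ]
  if (anyNA(g$gene_id))
    stop("gene(s) without coordinates: ",
         names(identities)[is.na(g$gene_id)][1])
  if (is.null(chrom_lengths)) {
    top <- if ("end" %in% names(g)) g$end else g$start + 1
    chrom_lengths <- tapply(top, g$chrom, max)
  }
  win <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    s <- seq(0, max(chrom_lengths[[ch]] - 1, 0), by = window_size)
    data.frame(chrom = ch, start = s,
               end = pmin(s + window_size, chrom_lengths[[ch]]))
  }))
  key <- paste0(win$chrom, ":", win$start / window_size)
  gw <- factor(paste0(g$chrom, ":", floor(g$start / window_size)),
               levels = key)
  win$mean_identity <- as.numeric(tapply(unname(identities), gw, mean))
  win$n <- as.numeric(table(gw))
  win
}

#' Misquantification enrichment inside introgression truth blocks
#'
#' Splits classified genes into introgressed (inside a truth block) and
#' background, tabulates incorrect (under- or overestimated) versus correct,
#' reports the misquantification rate in each stratum and a standard
#' chi-squared statistic on the 2x2 table (no continuity correction).
#'
#' @param classes a [classify_quantification()] result, or any data frame
#'   with `gene_id` and logical `incorrect` (e.g. a
#'   [compare_cultivars()] result).
#' @param introgressed_genes character vector of gene ids inside truth
#'   blocks (e.g. from [introgressed_genes()]).
#' @return a list of class `enrichment_report`: 2x2 `table`,
#'   `rate_introgressed`, `rate_background` (percent; `NA` when a stratum
#'   is empty), `chi_squared`, `p_value` (both `NA` on degenerate margins).
#' @export
enrichment_report <- function(classes, introgressed_genes) {
  df <- as.data.frame(classes)
  incorrect <- if ("incorrect" %in% names(df)) df$incorrect else
    df$class != "correct"
  inside <- df$gene_id %in% introgressed_genes
  tab <- table(factor(ifelse(inside, "introgressed", "background"),
                      levels = c("introgressed", "background")),
               factor(ifelse(incorrect, "incorrect", "correct"),
                      levels = c("incorrect", "correct")))
  rate <- function(stratum) {
    n <- sum(tab[stratum, ])
    if (n == 0) NA_real_ else 100 * tab[stratum, "incorrect"] / n
  }
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    chi <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(table = tab,
                 rate_introgressed = rate("introgressed"),
                 rate_background = rate("background"),
                 chi_squared = chi, p_value = p),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("Misquantification enrichment in introgressed regions\n")
  print(x$table)
  cat(sprintf("  rate introgressed: %s%%\n  rate background:   %s%%\n",
              format(x$rate_introgressed, digits = 4),
              format(x$rate_background, digits = 4)))
  if (is.na(x$chi_squared)) {
    cat("  chi-squared: undefined (degenerate margins)\n")
  } else {
    cat(sprintf("  chi-squared = %.4g, p = %.3g\n",
                x$chi_squared, x$p_value))
  }
  invisible(x)
}
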