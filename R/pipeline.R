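#' Run a full reference-bias experiment on a synthetic pangenome
#'
#' Orchestrates one experimental arm: simulate reads from a source cultivar,
#' build the requested reference index, pseudoalign and quantify with even
#' splitting, collapse to reference gene level, classify quantification
#' accuracy over the eligible gene set, and classify triad balance.
#'
#' Modes:
#' \describe{
#'   \item{`self_map`}{reference reads against the reference transcriptome.}
#'   \item{`cross_map`}{cultivar reads against the reference transcriptome.}
#'   \item{`pan_map`}{cultivar reads against the pantranscriptome (all
#'     cultivars' 1-to-1 transcripts), with orthologue count summing.}
#' }
#'
#' @param pangenome a [generate_pangenome()] result.
#' @param mode one of `"self_map"`, `"cross_map"`, `"pan_map"`.
#' @param cultivar read-source cultivar; default the reference for
#'   `self_map`, the first non-reference cultivar otherwise.
#' @param read_params a [read_sim_params()].
#' @param k k-mer length for the index.
#' @param missing_kmers pseudoalignment semantics; see [pseudoalign()].
#' @param exclude_cultivars cultivars whose transcripts are dropped from
#'   the pan reference (pan_map only; for leave-one-out experiments).
#' @param lower,upper classification bounds on estimated counts.
#' @return an object of class `bias_run`: a list with `gene_table`
#'   (gene_id, truth, est_count, class over the eligible set),
#'   `class_summary`, `triads` ([triad_balance()]), `triad_summary`,
#'   `enrichment` ([enrichment_report()], `NULL` when no truth blocks),
#'   and the resolved parameters.
#' @export
run_pipeline <- function(pangenome,
                         mode = c("self_map", "cross_map", "pan_map"),
                         cultivar = NULL,
                         read_params = read_sim_params(),
                         k = 31L,
                         missing_kmers = "strict",
                         exclude_cultivars = character(),
                         lower = 500, upper = 1500) {
  stopifnot(inherits(pangenome, "pangenome"))
  mode <- match.arg(mode)
  ref <- pangenome$cultivars[1]
  if (is.null(cultivar))
    cultivar <- if (mode == "self_map") ref else pangenome$cultivars[2]
  if (mode == "self_map" && cultivar != ref)
    stop("self_map mode simulates reads from the reference cultivar")

  src_tx <- transcripts(pangenome, cultivar)
  reads <- simulate_reads(src_tx, read_params)
  simulated_src <- sub("\\.[0-9]+$", "", unique(reads$gene))

  ref_tx <- transcripts(pangenome, ref)
  ref_reads_sim <- names(ref_tx)[nchar(ref_tx) >=
                                   read_params$min_transcript_length]
  simulated_ref <- sub("\\.[0-9]+$", "", ref_reads_sim)

  if (mode == "pan_map") {
    cvs <- setdiff(pangenome$cultivars[-1], exclude_cultivars)
    pan <- build_pantranscriptome(
      ref_tx,
      setNames(lapply(cvs, transcripts, pangenome = pangenome), cvs),
      pangenome$orthology, reference_name = ref)
    index <- build_index(pan$seqs, k = k)
    quant <- quantify(index, reads, missing_kmers = missing_kmers)
    genes <- sum_orthologue_counts(quant, pan)
  } else {
    index <- build_index(ref_tx, k = k)
    quant <- quantify(index, reads, missing_kmers = missing_kmers)
    genes <- aggregate_to_gene(quant)
  }
  counts <- setNames(genes$est_count, genes$gene_id)

  eligible <- if (mode == "self_map") {
    cross_mapping_gene_set(simulated_ref)
  } else {
    cross_mapping_gene_set(simulated_ref, simulated_src,
                           pangenome$orthology, cultivar)
  }
  truth <- setNames(rep(read_params$pairs_per_gene, length(eligible)),
                    eligible)
  est <- counts[eligible]
  est[is.na(est)] <- 0
  classes <- classify_quantification(setNames(unname(est), eligible),
                                     lower = lower, upper = upper)
  classes$truth <- unname(truth)

  # triads whose three homoeologues are all in the eligible gene set
  tr <- pangenome$triads
  keep <- tr$triad_id[tr$gene_A %in% eligible & tr$gene_B %in% eligible &
                        tr$gene_D %in% eligible]
  balances <- triad_balance(counts, tr, keep_triads = keep)

  enr <- NULL
  if (mode != "self_map" && nrow(pangenome$introgressions) > 0) {
    enr <- enrichment_report(classes,
                             introgressed_genes(pangenome, cultivar))
  }

  structure(list(mode = mode, cultivar = cultivar,
                 gene_table = classes,
                 class_summary = summary(classes),
                 triads = balances,
                 triad_summary = category_summary(balances),
                 enrichment = enr,
                 unassigned = attr(genes, "unassigned"),
                 params = list(k = k, missing_kmers = missing_kmers,
                               read_params = read_params,
                               lower = lower, upper = upper,
                               exclude_cultivars = exclude_cultivars)),
            class = "bias_run")
}

#' @export
print.bias_run <- function(x, ...) {
  cat("bias_run (", x$mode, ", reads from '", x$cultivar, "')\n", sep = "")
  cs <- x$class_summary
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-14s %6d  (%.2f%%)\n", cs$class[i], cs$n[i],
                cs$percent[i]))
  bal <- x$triad_summary
  b <- bal$percent[bal$category == "Balanced"]
  cat(sprintf("  triads balanced: %.2f%% of %d classified\n",
              if (length(b)) b else 0, sum(bal$n)))
  if (!is.null(x$enrichment))
    cat(sprintf("  misquantified: %.1f%% introgressed vs %.2f%% background\n",
                x$enrichment$rate_introgressed,
                x$enrichment$rate_background))
  invisible(x)
}

#' Read a pipeline run configuration
#'
#' Flat YAML of key-value pairs mirroring [run_pipeline()]'s arguments and
#' the generator/read-simulation defaults (k = 31, 1000 pairs of 150 bp
#' reads, 400 bp insert, 500/1500 count bounds, 1.5x fold rule, windowed
#' scores and deviation flagging at prob 0.99). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return named list of configuration values, defaults filled in.
#' @export
read_run_config <- function(path) {
  defaults <- list(mode = "self_map", cultivar = NULL, k = 31L,
                   missing_kmers = "strict",
                   pairs_per_gene = 1000L, read_length = 150L,
                   insert_size = 400L, min_transcript_length = 500L,
                   lower = 500, upper = 1500, fold = 1.5,
                   score_window_size = 5e6, coverage_window_size = 1e6,
                   outlier_prob = 0.99, seed = 1L)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}
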