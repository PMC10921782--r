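#' Parameters for error-free paired-end read simulation
#'
#' Defaults replicate the standard wgsim-style RNA protocol for benchmarking
#' reference bias: 1000 pairs of 150 bp reads per gene with a 400 bp insert
#' and no sequencing errors, simulated from the longest transcript of each
#' gene provided the transcript is at least 500 bp.
#'
#' @param pairs_per_gene read pairs emitted per eligible gene.
#' @param read_length read (mate) length in bp.
#' @param insert_size fragment length in bp; fixed, no jitter, so every mate
#'   is an exact substring (or reverse complement) of its transcript.
#' @param min_transcript_length genes with shorter transcripts emit no reads.
#' @param error_rate per-base error rate; fixed at 0, exposed for
#'   completeness and validated to be 0.
#' @param seed integer RNG seed.
#' @return an object of class `read_sim_params`.
#' @export
read_sim_params <- function(pairs_per_gene = 1000L, read_length = 150L,
                            insert_size = 400L,
                            min_transcript_length = 500L,
                            error_rate = 0, seed = 1L) {
  stopifnot(pairs_per_gene >= 1, read_length >= 1)
  if (insert_size < read_length)
    stop("insert_size must be >= read_length")
  if (min_transcript_length < insert_size)
    stop("min_transcript_length must be >= insert_size")
  if (error_rate != 0)
    stop("only error-free simulation is supported (error_rate = 0)")
  structure(list(pairs_per_gene = as.integer(pairs_per_gene),
                 read_length = as.integer(read_length),
                 insert_size = as.integer(insert_size),
                 min_transcript_length = as.integer(min_transcript_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate error-free read pairs from a transcript set
#'
#' Fragment start positions are drawn uniformly on
#' `[0, length - insert_size]` per pair. Mate 1 is the sense strand of the
#' fragment's 5' end; mate 2 is the reverse complement of its 3' end (FR
#' orientation). Pair ids encode the source gene and pair index
#' (`<transcript>|<i>`) so truth counts are recoverable without auxiliary
#' files.
#'
#' @param transcripts named character vector, one (longest) transcript per
#'   gene.
#' @param params a [read_sim_params()].
#' @return an object of class `read_pairs`: a list with vectors `id`,
#'   `gene` (source transcript name), `start` (0-based fragment start),
#'   `mate1`, `mate2`, and the `params` used.
#' @export
simulate_reads <- function(transcripts, params = read_sim_params()) {
  stopifnot(length(transcripts) > 0, !is.null(names(transcripts)),
            inherits(params, "read_sim_params"))
  set.seed(params$seed)
  len <- nchar(transcripts)
  eligible <- len >= params$min_transcript_length
  tx <- transcripts[eligible]
  ltx <- len[eligible]
  n <- length(tx) * params$pairs_per_gene
  if (n == 0) {
    return(structure(list(id = character(), gene = character(),
                          start = integer(), mate1 = character(),
                          mate2 = character(), params = params),
                     class = "read_pairs"))
  }
  gene <- rep(names(tx), each = params$pairs_per_gene)
  lrep <- rep(ltx, each = params$pairs_per_gene)
  seqrep <- rep(unname(tx), each = params$pairs_per_gene)
  # uniform over the (L - insert + 1) possible 0-based starts
  start <- floor(runif(n) * (lrep - params$insert_size + 1))
  start <- pmin(start, lrep - params$insert_size)  # guard fp edge
  rl <- params$read_length
  ins <- params$insert_size
  mate1 <- substr(seqrep, start + 1, start + rl)
  mate2 <- revcomp(substr(seqrep, start + ins - rl + 1, start + ins))
  id <- paste0(gene, "|", sequence(rep(params$pairs_per_gene, length(tx))))
  structure(list(id = id, gene = gene, start = as.integer(start),
                 mate1 = mate1, mate2 = mate2, params = params),
            class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs:", length(x$id), "pairs from",
      length(unique(x$gene)), "transcripts (",
      x$params$read_length, "bp mates, insert",
      x$params$insert_size, "bp)\n")
  invisible(x)
}

#' True read-pair counts per gene encoded in pair ids
#'
#' @param pairs a `read_pairs` object.
#' @param transcript_to_gene optional map from transcript name to gene id;
#'   default strips a trailing `.N` isoform suffix.
#' @return named numeric vector of simulated pairs per gene.
#' @export
truth_counts <- function(pairs, transcript_to_gene = NULL) {
  gene <- if (is.null(transcript_to_gene)) {
    sub("\\.[0-9]+$", "", pairs$gene)
  } else {
    unname(transcript_to_gene[pairs$gene])
  }
  tab <- table(gene)
  setNames(as.numeric(tab), names(tab))
}

#' Simulate a windowed DNA-coverage count matrix
#'
#' Stands in for the DNA arm of an introgression scan: per line and genomic
#' window, mapped-read counts are drawn Poisson(depth x multiplier), where
#' event blocks override the multiplier (0 = deletion, values below 1 =
#' divergent/introgressed material with reduced mappability). Windows tile
#' each chromosome 0-based half-open; the last window may be short.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths, or a
#'   `pangenome` (its reference genome is used).
#' @param lines character vector of line names, or a single count.
#' @param window_size window width in bp (the field standard is 1 Mbp;
#'   scaled-down genomes use proportionally smaller windows).
#' @param depth mean reads per window in unaffected windows.
#' @param events data frame with columns `line`, `chrom`, `start`, `end`,
#'   `multiplier`; a window receives an event's multiplier when it overlaps
#'   `[start, end)`.
#' @param seed integer RNG seed.
#' @return an object of class `window_counts`: data frame `line`, `chrom`,
#'   `start`, `end`, `count`.
#' @export
simulate_window_counts <- function(chrom_lengths, lines, window_size,
                                   depth, events = NULL, seed = 1L) {
  if (inherits(chrom_lengths, "pangenome")) {
    g <- chrom_lengths$genomes[[chrom_lengths$cultivars[1]]]
    chrom_lengths <- setNames(nchar(g), names(g))
  }
  stopifnot(window_size > 0, depth >= 0, !is.null(names(chrom_lengths)))
  if (is.numeric(lines) && length(lines) == 1)
    lines <- sprintf("line%03d", seq_len(lines))
  windows <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    s <- seq(0, chrom_lengths[[ch]] - 1, by = window_size)
    data.frame(chrom = ch, start = s,
               end = pmin(s + window_size, chrom_lengths[[ch]]))
  }))
  if (!is.null(events)) {
    stopifnot(all(c("line", "chrom", "start", "end", "multiplier") %in%
                    names(events)))
    if (any(events$multiplier < 0)) stop("multipliers must be >= 0")
    for (i in seq_len(nrow(events))) {
      if (!events$chrom[i] %in% names(chrom_lengths) ||
          events$start[i] < 0 ||
          events$end[i] > chrom_lengths[[events$chrom[i]]])
        stop("event ", i, " lies outside chromosome bounds")
      if (!events$line[i] %in% lines)
        stop("event ", i, " names unknown line '", events$line[i], "'")
    }
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(lines, function(ln) {
    mult <- rep(1, nrow(windows))
    if (!is.null(events)) {
      ev <- events[events$line == ln, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        hit <- windows$chrom == ev$chrom[i] &
          windows$start < ev$end[i] & windows$end > ev$start[i]
        mult[hit] <- ev$multiplier[i]
      }
    }
    data.frame(line = ln, chrom = windows$chrom, start = windows$start,
               end = windows$end,
               count = rpois(nrow(windows), depth * mult))
  }))
  rownames(out) <- NULL
  class(out) <- c("window_counts", "data.frame")
  out
}
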