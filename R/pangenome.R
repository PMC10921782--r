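#' Configure a synthetic allohexaploid pangenome
#'
#' Defines the conditions for [generate_pangenome()]: a reference cultivar
#' plus derived cultivars, each carrying three subgenomes (A, B, D) with one
#' chromosome per subgenome and `n_triads` genes per chromosome. Homoeologues
#' within a triad descend from a common ancestor mutated at
#' `subgenome_divergence`; cultivar orthologues descend from the reference
#' allele at `baseline_divergence`, except inside introgression blocks where
#' the block's own divergence applies.
#'
#' All divergence parameters are per-base substitution probabilities; no
#' indels are simulated, so orthologues stay length-matched and percent
#' identity of a pair is approximately `100 * (1 - rate)`.
#'
#' @param n_triads number of homoeologue triads (genes per chromosome).
#' @param n_cultivars number of cultivars including the reference (>= 2).
#' @param subgenome_divergence substitution rate separating each homoeologue
#'   from the triad ancestor. The default 0.04 keeps homoeologues
#'   distinguishable by 31-mers with very high probability.
#' @param baseline_divergence substitution rate between reference and
#'   cultivar alleles outside introgressions. The default 4e-4 gives
#'   orthologue identity of about 99.95%, emulating the near-identical
#'   background of elite bread-wheat cultivars.
#' @param introgressions list of [introgression()] specs.
#' @param gene_length_range integer range (min, max) of CDS lengths in bp;
#'   min must be >= 500 so reads are simulable.
#' @param intergenic_gap bp of random sequence between consecutive genes.
#' @param missing_orthologue_rate probability a cultivar lacks a reference
#'   gene entirely (presence/absence variation).
#' @param duplication_rate probability a cultivar carries a tandem duplicate
#'   of a gene (copy-number variation).
#' @param strand_randomization place genes on random strands (default all
#'   forward).
#' @param cultivar_names optional character vector of cultivar names; first
#'   is the reference. Default `ref`, `cv1`, `cv2`, ...
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   config.
#' @return an object of class `pangenome_config`.
#' @seealso [generate_pangenome()], [introgression()]
#' @export
pangenome_config <- function(n_triads = 150, n_cultivars = 3,
                             subgenome_divergence = 0.04,
                             baseline_divergence = 4e-4,
                             introgressions = list(),
                             gene_length_range = c(900L, 1500L),
                             intergenic_gap = 500L,
                             missing_orthologue_rate = 0,
                             duplication_rate = 0,
                             strand_randomization = FALSE,
                             cultivar_names = NULL,
                             seed = 1L) {
  stopifnot(n_triads >= 1, n_cultivars >= 2)
  rates <- c(subgenome_divergence, baseline_divergence,
             missing_orthologue_rate, duplication_rate)
  if (any(rates < 0 | rates >= 1)) stop("all rates must lie in [0, 1)")
  if (length(gene_length_range) != 2 || gene_length_range[1] < 500)
    stop("gene_length_range minimum must be >= 500 bp")
  if (gene_length_range[2] < gene_length_range[1])
    stop("gene_length_range must be (min, max)")
  if (is.null(cultivar_names))
    cultivar_names <- c("ref", paste0("cv", seq_len(n_cultivars - 1)))
  if (length(cultivar_names) != n_cultivars ||
      anyDuplicated(cultivar_names))
    stop("cultivar_names must be ", n_cultivars, " unique names")
  chroms <- c("chr1A", "chr1B", "chr1D")
  for (sp in introgressions) {
    if (!inherits(sp, "introgression_spec"))
      stop("introgressions must be a list of introgression() specs")
    if (!sp$cultivar %in% cultivar_names[-1])
      stop("introgression cultivar '", sp$cultivar,
           "' is not a non-reference cultivar")
    if (!sp$chromosome %in% chroms)
      stop("unknown chromosome '", sp$chromosome, "'")
    if (sp$first_gene + sp$n_genes - 1 > n_triads)
      stop("introgression block exceeds chromosome capacity (",
           n_triads, " genes)")
  }
  # non-overlap within each cultivar/chromosome
  key <- vapply(introgressions, function(s)
    paste(s$cultivar, s$chromosome), "")
  for (k in unique(key)) {
    sp <- introgressions[key == k]
    if (length(sp) > 1) {
      iv <- t(vapply(sp, function(s)
        c(s$first_gene, s$first_gene + s$n_genes - 1), c(0, 0)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop("overlapping introgression blocks for ", k)
    }
  }
  structure(list(n_triads = as.integer(n_triads),
                 n_cultivars = as.integer(n_cultivars),
                 cultivar_names = cultivar_names,
                 chromosomes = chroms,
                 subgenome_divergence = subgenome_divergence,
                 baseline_divergence = baseline_divergence,
                 introgressions = introgressions,
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_gap = as.integer(intergenic_gap),
                 missing_orthologue_rate = missing_orthologue_rate,
                 duplication_rate = duplication_rate,
                 strand_randomization = isTRUE(strand_randomization),
                 seed = as.integer(seed)),
            class = "pangenome_config")
}

#' Specify one introgression block
#'
#' A contiguous run of genes in one cultivar whose alleles derive from a
#' divergent donor haplotype instead of the reference allele. Blocks sharing
#' a `donor` label (and position) produce byte-identical haplotypes across
#' cultivars, emulating a shared introgression with no recombination since
#' its introduction.
#'
#' @param cultivar non-reference cultivar carrying the block.
#' @param chromosome chromosome name (`chr1A`, `chr1B` or `chr1D`).
#' @param first_gene 1-based index of the first gene in the block.
#' @param n_genes number of consecutive genes in the block.
#' @param divergence per-base substitution rate of the donor haplotype
#'   relative to the reference allele (e.g. 0.03 for ~97% identity).
#' @param donor label of the donor haplotype; defaults to a label unique to
#'   this spec.
#' @return an object of class `introgression_spec`.
#' @export
introgression <- function(cultivar, chromosome, first_gene, n_genes,
                          divergence, donor = NULL) {
  stopifnot(first_gene >= 1, n_genes >= 1, divergence >= 0, divergence < 1)
  if (is.null(donor))
    donor <- paste0("donor_", cultivar, "_", chromosome, "_", first_gene)
  structure(list(cultivar = cultivar, chromosome = chromosome,
                 first_gene = as.integer(first_gene),
                 n_genes = as.integer(n_genes),
                 divergence = divergence, donor = donor),
            class = "introgression_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base with probability `rate` (always to a different base)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b)
      sample(bases[bases != b], 1L), "", USE.NAMES = FALSE)
  }
  paste(v, collapse = "")
}

# deterministic small-integer hash for donor haplotype sub-seeding
str_hash <- function(s) {
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 131 + cc) %% 2147483629
  as.integer(h)
}

#' Generate a synthetic pangenome
#'
#' Builds the reference cultivar from seeded random nucleotides (one random
#' ancestor per triad, mutated independently into the A, B and D
#' homoeologues), then derives each non-reference cultivar gene-by-gene:
#' baseline substitutions outside introgression blocks, donor-haplotype
#' substitutions inside them, with optional missing orthologues and tandem
#' duplications. Chromosomes are assembled as alternating intergenic gaps
#' and gene bodies; all coordinates are 0-based half-open.
#'
#' @param config a [pangenome_config()].
#' @return an object of class `pangenome`: a list with elements
#'   \describe{
#'     \item{genes}{data frame of all gene records (`cultivar`, `gene_id`,
#'       `chrom`, `start`, `end`, `strand`, `triad`, `cds`).}
#'     \item{genomes}{per-cultivar named character vectors of chromosome
#'       sequences.}
#'     \item{triads}{data frame `triad_id`, `gene_A`, `gene_B`, `gene_D`
#'       (reference gene ids).}
#'     \item{orthology}{data frame `cultivar`, `cultivar_gene`,
#'       `reference_gene`, `relationship` (one_to_one / missing /
#'       duplicated).}
#'     \item{introgressions}{truth blocks in reference coordinates
#'       (`cultivar`, `chrom`, `start`, `end`, `donor`, `divergence`) plus
#'       the reference gene ids they cover (list column `genes`).}
#'   }
#' @examples
#' pg <- generate_pangenome(pangenome_config(n_triads = 5, seed = 42))
#' head(pg$genes[, 1:6])
#' @export
generate_pangenome <- function(config) {
  stopifnot(inherits(config, "pangenome_config"))
  set.seed(config$seed)
  nt <- config$n_triads
  cvs <- config$cultivar_names
  ref <- cvs[1]
  chroms <- config$chromosomes
  subg <- c(chr1A = "A", chr1B = "B", chr1D = "D")

  lens <- sample(seq(config$gene_length_range[1],
                     config$gene_length_range[2]), nt, replace = TRUE)
  ancestors <- vapply(lens, random_dna, "")
  hom <- lapply(chroms, function(ch)
    vapply(ancestors, mutate_seq, "", rate = config$subgenome_divergence))
  names(hom) <- chroms
  gaps <- lapply(chroms, function(ch)
    vapply(rep(config$intergenic_gap, nt + 1), random_dna, ""))
  names(gaps) <- chroms
  strands <- if (config$strand_randomization) {
    lapply(chroms, function(ch) sample(c("+", "-"), nt, replace = TRUE))
  } else {
    lapply(chroms, function(ch) rep("+", nt))
  }
  names(strands) <- chroms

  # donor haplotypes shared across cultivars via donor-label sub-seeds
  donors <- sort(unique(vapply(config$introgressions,
                               function(s) s$donor, "")))
  donor_seed <- setNames(derive_seeds(length(donors)), donors)
  cv_seed <- setNames(derive_seeds(length(cvs) - 1), cvs[-1])
  pav_seed <- setNames(derive_seeds(length(cvs) - 1), cvs[-1])

  gene_id <- function(cv, ch, i)
    sprintf("%s.%s.g%03d", cv, ch, i)

  gene_rows <- list()
  genomes <- list()
  orth_rows <- list()

  assemble <- function(cv, cds_by_chrom) {
    # cds_by_chrom: list chrom -> data.frame(gene_id, triad, cds)
    rows <- list()
    gg <- character(length(chroms))
    names(gg) <- chroms
    for (ch in chroms) {
      df <- cds_by_chrom[[ch]]
      pieces <- character(2 * nrow(df) + 1)
      pieces[1] <- gaps[[ch]][1]
      pos <- nchar(gaps[[ch]][1])
      start <- integer(nrow(df))
      end <- integer(nrow(df))
      for (i in seq_len(nrow(df))) {
        body <- if (df$strand[i] == "-") revcomp(df$cds[i]) else df$cds[i]
        pieces[2 * i] <- body
        start[i] <- pos
        pos <- pos + nchar(body)
        end[i] <- pos
        gi <- min(df$triad[i] + 1, nt + 1)
        pieces[2 * i + 1] <- gaps[[ch]][gi]
        pos <- pos + nchar(gaps[[ch]][gi])
      }
      gg[ch] <- paste(pieces, collapse = "")
      rows[[ch]] <- data.frame(cultivar = cv, gene_id = df$gene_id,
                               chrom = ch, start = start, end = end,
                               strand = df$strand, triad = df$triad,
                               cds = df$cds, stringsAsFactors = FALSE)
    }
    list(genes = do.call(rbind, rows), genome = gg)
  }

  # reference cultivar
  ref_cds <- lapply(chroms, function(ch)
    data.frame(gene_id = gene_id(ref, ch, seq_len(nt)),
               triad = seq_len(nt), cds = unname(hom[[ch]]),
               strand = strands[[ch]], stringsAsFactors = FALSE))
  names(ref_cds) <- chroms
  asm <- assemble(ref, ref_cds)
  gene_rows[[ref]] <- asm$genes
  genomes[[ref]] <- asm$genome

  # introgression lookup: cultivar -> chrom -> per-gene (divergence, donor)
  intro_of <- function(cv, ch, i) {
    for (sp in config$introgressions) {
      if (sp$cultivar == cv && sp$chromosome == ch &&
          i >= sp$first_gene && i < sp$first_gene + sp$n_genes)
        return(sp)
    }
    NULL
  }

  intro_truth <- list()
  for (cv in cvs[-1]) {
    set.seed(cv_seed[cv])
    cds_list <- list()
    for (ch in chroms) {
      ids <- gene_id(cv, ch, seq_len(nt))
      cds <- character(nt)
      for (i in seq_len(nt)) {
        sp <- intro_of(cv, ch, i)
        if (is.null(sp)) {
          cds[i] <- mutate_seq(hom[[ch]][i], config$baseline_divergence)
        } else {
          # donor haplotype: deterministic per (donor, chrom, gene)
          saved <- get(".Random.seed", envir = .GlobalEnv)
          set.seed((donor_seed[sp$donor] + 977L * i) %% 2147483629)
          cds[i] <- mutate_seq(hom[[ch]][i], sp$divergence)
          assign(".Random.seed", saved, envir = .GlobalEnv)
        }
      }
      cds_list[[ch]] <- data.frame(gene_id = ids, triad = seq_len(nt),
                                   cds = cds, strand = strands[[ch]],
                                   stringsAsFactors = FALSE)
    }
    # presence/absence and tandem duplication
    set.seed(pav_seed[cv])
    orth <- list()
    for (ch in chroms) {
      df <- cds_list[[ch]]
      u <- runif(nt)
      v <- runif(nt)
      missing <- u < config$missing_orthologue_rate
      dup <- !missing & v < config$duplication_rate
      ref_ids <- gene_id(ref, ch, seq_len(nt))
      rel <- ifelse(missing, "missing",
                    ifelse(dup, "duplicated", "one_to_one"))
      orth[[ch]] <- data.frame(cultivar = cv,
                               cultivar_gene = ifelse(missing, NA, df$gene_id),
                               reference_gene = ref_ids,
                               relationship = rel, stringsAsFactors = FALSE)
      if (any(dup)) {
        extra <- df[dup, , drop = FALSE]
        extra$gene_id <- paste0(extra$gene_id, "d")
        orth[[ch]] <- rbind(orth[[ch]],
          data.frame(cultivar = cv, cultivar_gene = extra$gene_id,
                     reference_gene = ref_ids[dup],
                     relationship = "duplicated", stringsAsFactors = FALSE))
        # interleave duplicates right after their template (tandem)
        ord <- order(c(which(!missing), which(dup) + 0.5))
        df <- rbind(df[!missing, , drop = FALSE], extra)[ord, , drop = FALSE]
      } else {
        df <- df[!missing, , drop = FALSE]
      }
      cds_list[[ch]] <- df
    }
    asm <- assemble(cv, cds_list)
    gene_rows[[cv]] <- asm$genes
    genomes[[cv]] <- asm$genome
    orth_rows[[cv]] <- do.call(rbind, orth)
  }

  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  orthology <- if (length(orth_rows)) do.call(rbind, orth_rows) else
    data.frame(cultivar = character(), cultivar_gene = character(),
               reference_gene = character(), relationship = character())
  rownames(orthology) <- NULL

  triads <- data.frame(triad_id = sprintf("t%03d", seq_len(nt)),
                       gene_A = gene_id(ref, "chr1A", seq_len(nt)),
                       gene_B = gene_id(ref, "chr1B", seq_len(nt)),
                       gene_D = gene_id(ref, "chr1D", seq_len(nt)),
                       stringsAsFactors = FALSE)

  ref_genes <- genes[genes$cultivar == ref, ]
  for (sp in config$introgressions) {
    idx <- seq(sp$first_gene, sp$first_gene + sp$n_genes - 1)
    ids <- gene_id(ref, sp$chromosome, idx)
    g <- ref_genes[match(ids, ref_genes$gene_id), ]
    intro_truth[[length(intro_truth) + 1]] <-
      data.frame(cultivar = sp$cultivar, chrom = sp$chromosome,
                 start = min(g$start), end = max(g$end),
                 donor = sp$donor, divergence = sp$divergence,
                 genes = I(list(ids)), stringsAsFactors = FALSE)
  }
  introgressions <- if (length(intro_truth)) do.call(rbind, intro_truth) else
    data.frame(cultivar = character(), chrom = character(),
               start = integer(), end = integer(), donor = character(),
               divergence = numeric(), genes = I(list()))
  rownames(introgressions) <- NULL

  structure(list(config = config, cultivars = cvs, genes = genes,
                 genomes = genomes, triads = triads, orthology = orthology,
                 introgressions = introgressions),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat("Synthetic pangenome: ", length(x$cultivars),
      " cultivars (reference '", x$cultivars[1], "'), ", nrow(x$triads),
      " triads, ", nrow(x$introgressions), " introgression block(s)\n",
      sep = "")
  invisible(x)
}

#' Extract a cultivar's transcript set
#'
#' One transcript per gene, named `<gene_id>.1`, holding the forward-strand
#' CDS.
#'
#' @param pangenome a [generate_pangenome()] result.
#' @param cultivar cultivar name.
#' @return named character vector of transcript sequences.
#' @export
transcripts <- function(pangenome, cultivar) {
  stopifnot(inherits(pangenome, "pangenome"),
            cultivar %in% pangenome$cultivars)
  g <- pangenome$genes[pangenome$genes$cultivar == cultivar, ]
  setNames(g$cds, paste0(g$gene_id, ".1"))
}

#' Reference gene ids inside a cultivar's introgression blocks
#'
#' @param pangenome a [generate_pangenome()] result.
#' @param cultivar cultivar name; default all cultivars.
#' @return character vector of reference gene ids.
#' @export
introgressed_genes <- function(pangenome, cultivar = NULL) {
  tr <- pangenome$introgressions
  if (!is.null(cultivar)) tr <- tr[tr$cultivar %in% cultivar, ]
  unique(unlist(tr$genes))
}

#' Write a pangenome to disk
#'
#' Emits, per cultivar, a transcript FASTA and a genome FASTA, plus four
#' tables: gene coordinates (BED-like TSV, 0-based half-open), orthology
#' TSV, triad TSV and an introgression-truth BED in reference coordinates.
#'
#' @param pangenome a [generate_pangenome()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of paths written.
#' @export
write_pangenome <- function(pangenome, dir) {
  stopifnot(inherits(pangenome, "pangenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cv in pangenome$cultivars) {
    p1 <- file.path(dir, paste0(cv, ".transcripts.fasta"))
    write_fasta(transcripts(pangenome, cv), p1)
    p2 <- file.path(dir, paste0(cv, ".genome.fasta"))
    write_fasta(pangenome$genomes[[cv]], p2)
    paths <- c(paths, p1, p2)
  }
  p <- file.path(dir, "genes.tsv")
  write_tsv(pangenome$genes[, c("cultivar", "gene_id", "chrom", "start",
                                "end", "strand")], p)
  paths <- c(paths, p)
  p <- file.path(dir, "orthology.tsv")
  write_tsv(pangenome$orthology, p)
  paths <- c(paths, p)
  p <- file.path(dir, "triads.tsv")
  write_tsv(pangenome$triads, p)
  paths <- c(paths, p)
  p <- file.path(dir, "introgressions.bed")
  tr <- pangenome$introgressions
  bed <- if (nrow(tr)) {
    data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
               name = paste0(tr$cultivar, "|", tr$donor))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  }
  write_bed(bed, p)
  paths <- c(paths, p)
  invisible(paths)
}
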