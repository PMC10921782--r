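# Shared fixtures, built once per test run and memoised.
#
# The main fixture is the study-condition pangenome: 150 triads (450
# reference genes), a reference plus three cultivars at baseline divergence
# 4e-4, introgression blocks at 3% divergence (cv1 and cv3 share the same
# donor haplotype on chr1D; cv2 carries an independent block on chr1B),
# with low rates of missing and tandem-duplicated orthologues. Reads follow
# the standard protocol: 1000 error-free 150 bp pairs per gene, 400 bp
# insert, genes >= 500 bp.

fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = fx_cache)) assign(name, builder(), fx_cache)
  get(name, envir = fx_cache)
}

fx_config <- function() {
  pangenome_config(
    n_triads = 150, n_cultivars = 4, seed = 20260930,
    subgenome_divergence = 0.04, baseline_divergence = 4e-4,
    missing_orthologue_rate = 0.02, duplication_rate = 0.01,
    introgressions = list(
      introgression("cv1", "chr1D", 101, 30, 0.03, donor = "dA"),
      introgression("cv2", "chr1B", 31, 25, 0.03, donor = "dB"),
      introgression("cv3", "chr1D", 101, 30, 0.03, donor = "dA")))
}

fx_pangenome <- function() fx_get("pg", function() generate_pangenome(fx_config()))

fx_read_params <- function() read_sim_params(seed = 101)

fx_run <- function(mode, cultivar = NULL, exclude = character()) {
  key <- paste0("run_", mode, "_", cultivar %||% "ref",
                if (length(exclude)) paste0("_ex_", paste(exclude, collapse = "+")))
  fx_get(key, function()
    run_pipeline(fx_pangenome(), mode, cultivar = cultivar,
                 read_params = fx_read_params(), exclude_cultivars = exclude))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fixture for brute-force oracles (substring containment, identity)
fx_small_pangenome <- function() {
  fx_get("pg_small", function()
    generate_pangenome(pangenome_config(
      n_triads = 12, n_cultivars = 2, seed = 424242,
      introgressions = list(introgression("cv1", "chr1D", 5, 4, 0.03)))))
}

# Brute-force substring-containment compatibility oracle: a transcript is
# compatible with a mate when it contains the mate or its reverse
# complement; a pair's set is the intersection across mates.
oracle_compat_sets <- function(transcripts, pairs) {
  tx <- unname(transcripts)
  nm <- names(transcripts)
  rc1 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pairs$mate1)))
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pairs$mate2)))
  lapply(seq_along(pairs$mate1), function(i) {
    ok1 <- grepl(pairs$mate1[i], tx, fixed = TRUE) |
      grepl(rc1[i], tx, fixed = TRUE)
    ok2 <- grepl(pairs$mate2[i], tx, fixed = TRUE) |
      grepl(rc2[i], tx, fixed = TRUE)
    sort(nm[ok1 & ok2])
  })
}

# per-pair sets as returned by pseudoalign()
alignment_sets <- function(al) {
  lapply(al$assignment, function(a)
    if (a == 0L) character() else sort(al$sets[[a]]))
}

revcomp_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly `at` positions with a different base
mutate_at <- function(seq, at) {
  v <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in at) v[i] <- sample(bases[bases != v[i]], 1)
  paste(v, collapse = "")
}

# closed-form 2x2 chi-squared (no continuity correction)
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# percent identity for equal-length, indel-free pairs via edit distance
oracle_identity_adist <- function(x, y) {
  100 * (1 - drop(utils::adist(x, y)) / nchar(x))
}
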