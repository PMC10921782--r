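test_that("index construction: minimal, duplicate-sequence and canonical cases", {
  set.seed(10)
  s <- random_dna_test(31)
  idx <- build_index(c(t1.1 = s), k = 31)
  expect_equal(idx$n_kmers, 1)
  # two identical transcripts under different ids: every k-mer maps to both
  s2 <- random_dna_test(200)
  idx2 <- build_index(c(a.1 = s2, b.1 = s2), k = 31)
  expect_equal(idx2$n_ecs, 1)
  expect_setequal(pseudoalign_pair(idx2, substr(s2, 1, 60),
                                   revcomp_test(substr(s2, 101, 160))),
                  c("a.1", "b.1"))
  # a transcript and its reverse complement have identical canonical k-mer sets
  idx3 <- build_index(c(f.1 = s2, r.1 = revcomp_test(s2)), k = 31)
  expect_equal(idx3$n_kmers, idx2$n_kmers)
  expect_equal(idx3$n_ecs, 1)
  # duplicate ids rejected; short transcripts skipped with a warning
  expect_error(build_index(c(x.1 = s2, x.1 = s2)), "duplicate")
  expect_warning(build_index(c(a.1 = s2, tiny.1 = random_dna_test(20))),
                 "shorter than k")
})

test_that("pair compatibility follows intersection semantics", {
  set.seed(11)
  shared <- random_dna_test(500)
  t1 <- paste0(shared, random_dna_test(400))
  t2 <- paste0(shared, random_dna_test(400))
  t3 <- random_dna_test(900)
  idx <- build_index(c(t1.1 = t1, t2.1 = t2, t3.1 = t3))
  # pair from a region unique to t1
  expect_identical(pseudoalign_pair(idx, substr(t1, 520, 669),
                                    revcomp_test(substr(t1, 751, 900))),
                   "t1.1")
  # pair wholly within the shared region
  expect_setequal(pseudoalign_pair(idx, substr(shared, 1, 150),
                                   revcomp_test(substr(shared, 251, 400))),
                  c("t1.1", "t2.1"))
  # pair from a transcript absent from the index
  absent <- random_dna_test(600)
  expect_length(pseudoalign_pair(idx, substr(absent, 1, 150),
                                 revcomp_test(substr(absent, 251, 400))),
                0)
})

test_that("strict semantics void a mutated mate; skip semantics salvage it", {
  set.seed(12)
  t1 <- random_dna_test(800)
  idx <- build_index(c(t1.1 = t1))
  m1 <- substr(t1, 1, 150)
  m2 <- revcomp_test(substr(t1, 251, 400))
  m1_mut <- mutate_at(m1, 75)
  expect_length(pseudoalign_pair(idx, m1_mut, m2, "strict"), 0)
  expect_identical(pseudoalign_pair(idx, m1_mut, m2, "skip"), "t1.1")
  # a mate with no indexed k-mers leaves the pair unassigned in both modes
  noise <- random_dna_test(150)
  expect_length(pseudoalign_pair(idx, noise, m2, "strict"), 0)
  expect_length(pseudoalign_pair(idx, noise, m2, "skip"), 0)
})

test_that("even splitting: unique pairs count 1, shared pairs split, totals conserved", {
  set.seed(13)
  shared <- random_dna_test(500)
  t1 <- paste0(shared, random_dna_test(300))
  t2 <- paste0(shared, random_dna_test(300))
  idx <- build_index(c(t1.1 = t1, t2.1 = t2))
  uniq <- list(mate1 = rep(substr(t1, 510, 659), 10),
               mate2 = rep(revcomp_test(substr(t1, 651, 800)), 10))
  q <- quantify(idx, uniq)
  expect_equal(q$est_count[q$transcript_id == "t1.1"], 10)
  expect_equal(q$est_count[q$transcript_id == "t2.1"], 0)
  both <- list(mate1 = rep(substr(shared, 1, 150), 10),
               mate2 = rep(revcomp_test(substr(shared, 251, 400)), 10))
  q2 <- quantify(idx, both)
  expect_equal(q2$est_count, c(5, 5))
  mixed <- list(mate1 = c(uniq$mate1, both$mate1),
                mate2 = c(uniq$mate2, both$mate2))
  q3 <- quantify(idx, mixed)
  expect_equal(sum(q3$est_count), attr(q3, "assigned"))
  expect_equal(attr(q3, "assigned"), 20)
})

test_that("TPM follows the closed form and degenerate cases", {
  expect_equal(compute_tpm(rep(7, 4), rep(1000, 4)), rep(250000, 4))
  expect_equal(compute_tpm(c(10, 10), c(1000, 2000)),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(compute_tpm(c(0, 0), c(100, 200)), c(0, 0))
  q <- data.frame(est_count = c(3, 1), length = c(300, 100))
  expect_equal(sum(compute_tpm(q$est_count, q$length)), 1e6)
})

test_that("gene aggregation sums transcripts and conserves totals", {
  q <- structure(data.frame(transcript_id = c("g1.1", "g1.2", "g2.1"),
                            length = c(500, 400, 600),
                            est_count = c(3.5, 1.5, 2),
                            tpm = c(100, 50, 25)),
                 class = c("quant_table", "data.frame"))
  g <- aggregate_to_gene(q)
  expect_equal(g$est_count[g$gene_id == "g1"], 5.0)
  expect_equal(g$est_count[g$gene_id == "g2"], 2.0)
  expect_equal(sum(g$est_count), sum(q$est_count))
  expect_equal(sum(g$tpm), sum(q$tpm))
  # single-transcript genes reduce to the transcript table
  q2 <- q[3, ]
  expect_equal(aggregate_to_gene(q2)$est_count, q2$est_count)
  expect_error(aggregate_to_gene(q, c(g1.1 = "g1", g1.2 = "g1")),
               "without a gene mapping")
})

test_that("duplicating a transcript leaves gene-level counts unchanged", {
  set.seed(14)
  tx <- setNames(vapply(rep(700, 6), random_dna_test, ""),
                 paste0("g", 1:6, ".1"))
  rp <- simulate_reads(tx, read_sim_params(pairs_per_gene = 40, seed = 21,
                                           min_transcript_length = 500))
  base <- aggregate_to_gene(quantify(build_index(tx), rp))
  dup <- c(tx, setNames(tx, paste0("g", 1:6, ".2")))
  withdup <- aggregate_to_gene(quantify(build_index(dup), rp))
  expect_equal(withdup$est_count[match(base$gene_id, withdup$gene_id)],
               base$est_count, tolerance = 1e-12)
})

test_that("assigned count is monotone non-increasing in divergence of the read source", {
  set.seed(15)
  tx <- c(g1.1 = random_dna_test(900))
  idx <- build_index(tx)
  rates <- c(0, 0.005, 0.02, 0.08)
  counts <- vapply(seq_along(rates), function(i) {
    set.seed(300 + i)
    div <- mutate_at(tx[[1]], which(runif(900) < rates[i]))
    rp <- simulate_reads(c(g1.1 = div),
                         read_sim_params(pairs_per_gene = 200, seed = 77))
    sum(quantify(idx, rp)$est_count)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 200)         # zero divergence: full recovery
  expect_lt(counts[4], counts[1] / 10) # far beyond k/read-length: collapse
})

test_that("index persists to a binary artifact and restores identically", {
  set.seed(16)
  tx <- setNames(vapply(rep(600, 4), random_dna_test, ""),
                 paste0("g", 1:4, ".1"))
  idx <- build_index(tx, k = 25)
  p <- file.path(withr::local_tempdir(), "fixture.pqidx")
  write_index(idx, p)
  idx2 <- read_index(p)
  expect_equal(idx2$k, 25)
  expect_identical(idx2$tx_names, idx$tx_names)
  expect_equal(idx2$n_kmers, idx$n_kmers)
  rp <- simulate_reads(tx, read_sim_params(pairs_per_gene = 10, seed = 5))
  expect_equal(quantify(idx2, rp)$est_count, quantify(idx, rp)$est_count)
  bad <- file.path(withr::local_tempdir(), "not_an_index")
  writeLines("junk", bad)
  expect_error(read_index(bad), "version header")
})
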