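test_that("zero-divergence, zero-PAV config reproduces the reference in every cultivar", {
  pg <- generate_pangenome(pangenome_config(
    n_triads = 6, n_cultivars = 3, subgenome_divergence = 0,
    baseline_divergence = 0, seed = 3))
  ref_cds <- pg$genes$cds[pg$genes$cultivar == "ref"]
  for (cv in c("cv1", "cv2")) {
    expect_identical(pg$genes$cds[pg$genes$cultivar == cv], ref_cds)
  }
  expect_true(all(pg$orthology$relationship == "one_to_one"))
  # zero subgenome divergence: homoeologues are the ancestor itself
  tr <- pg$triads
  g <- pg$genes[pg$genes$cultivar == "ref", ]
  expect_identical(g$cds[match(tr$gene_A, g$gene_id)],
                   g$cds[match(tr$gene_B, g$gene_id)])
})

test_that("generation is deterministic: same config and seed give byte-identical output", {
  cfg <- pangenome_config(n_triads = 8, n_cultivars = 3, seed = 99,
                          missing_orthologue_rate = 0.1,
                          duplication_rate = 0.1,
                          introgressions = list(
                            introgression("cv1", "chr1A", 2, 3, 0.05)))
  pg1 <- generate_pangenome(cfg)
  pg2 <- generate_pangenome(cfg)
  expect_identical(pg1$genes, pg2$genes)
  expect_identical(pg1$genomes, pg2$genomes)
  expect_identical(pg1$orthology, pg2$orthology)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_pangenome(pg1, d1); write_pangenome(pg2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("introgressed orthologue pairs show ~97% identity, background ~100*(1-rate)%", {
  pg <- fx_small_pangenome()
  rt <- transcripts(pg, "ref")
  ct <- transcripts(pg, "cv1")
  intro <- introgressed_genes(pg, "cv1")
  orth <- pg$orthology
  id_of <- function(ref_gene) {
    cg <- orth$cultivar_gene[orth$reference_gene == ref_gene]
    cds_identity(rt[[paste0(ref_gene, ".1")]], ct[[paste0(cg, ".1")]])
  }
  ids_in <- vapply(intro, id_of, 0)
  bg <- setdiff(orth$reference_gene[orth$relationship == "one_to_one"], intro)
  ids_out <- vapply(bg, id_of, 0)
  expect_gt(mean(ids_in), 96)
  expect_lt(mean(ids_in), 98)
  expect_gt(mean(ids_out), 99.8)
  # cross-check the alignment-based identity with an edit-distance oracle
  for (g in intro[1:2]) {
    cg <- orth$cultivar_gene[orth$reference_gene == g]
    expect_equal(id_of(g),
                 oracle_identity_adist(rt[[paste0(g, ".1")]],
                                       ct[[paste0(cg, ".1")]]),
                 tolerance = 1e-9)
  }
})

test_that("gene CDS equals the genome substring at its coordinates, strand resolved", {
  pg <- generate_pangenome(pangenome_config(
    n_triads = 5, n_cultivars = 2, strand_randomization = TRUE, seed = 17))
  for (cv in pg$cultivars) {
    g <- pg$genes[pg$genes$cultivar == cv, ]
    for (i in seq_len(nrow(g))) {
      body <- substr(pg$genomes[[cv]][[g$chrom[i]]],
                     g$start[i] + 1, g$end[i])
      expected <- if (g$strand[i] == "-") {
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(g$cds[i])))
      } else g$cds[i]
      expect_identical(body, expected)
    }
  }
  expect_true(any(pg$genes$strand == "-"))
})

test_that("triads are complete and one-to-one orthology is bijective per cultivar", {
  pg <- fx_pangenome()
  tr <- pg$triads
  ref_g <- pg$genes[pg$genes$cultivar == "ref", ]
  expect_equal(nrow(tr), 150)
  expect_true(all(ref_g$chrom[match(tr$gene_A, ref_g$gene_id)] == "chr1A"))
  expect_true(all(ref_g$chrom[match(tr$gene_B, ref_g$gene_id)] == "chr1B"))
  expect_true(all(ref_g$chrom[match(tr$gene_D, ref_g$gene_id)] == "chr1D"))
  for (cv in pg$cultivars[-1]) {
    o <- pg$orthology[pg$orthology$cultivar == cv &
                        pg$orthology$relationship == "one_to_one", ]
    expect_false(anyDuplicated(o$cultivar_gene) > 0)
    expect_false(anyDuplicated(o$reference_gene) > 0)
  }
  # truth blocks cover exactly the genes drawn at the block rate
  expect_length(introgressed_genes(pg, "cv1"), 30)
  expect_identical(introgressed_genes(pg, "cv1"),
                   sprintf("ref.chr1D.g%03d", 101:130))
})

test_that("shared donor labels give identical introgressed haplotypes across cultivars", {
  pg <- fx_pangenome()
  t1 <- transcripts(pg, "cv1")
  t3 <- transcripts(pg, "cv3")
  orth <- pg$orthology
  for (g in introgressed_genes(pg, "cv1")[c(1, 15, 30)]) {
    c1 <- orth$cultivar_gene[orth$cultivar == "cv1" & orth$reference_gene == g]
    c3 <- orth$cultivar_gene[orth$cultivar == "cv3" & orth$reference_gene == g]
    if (length(c1) == 1 && length(c3) == 1 && !is.na(c1) && !is.na(c3))
      expect_identical(unname(t1[paste0(c1, ".1")]),
                       unname(t3[paste0(c3, ".1")]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(pangenome_config(baseline_divergence = 1), "rates")
  expect_error(pangenome_config(gene_length_range = c(400, 900)), ">= 500")
  expect_error(pangenome_config(introgressions = list(
    introgression("cv1", "chr1A", 140, 30, 0.03))), "capacity")
  expect_error(pangenome_config(introgressions = list(
    introgression("cv1", "chr1A", 5, 10, 0.03),
    introgression("cv1", "chr1A", 10, 5, 0.03))), "overlap")
  expect_error(pangenome_config(introgressions = list(
    introgression("ref", "chr1A", 1, 2, 0.03))), "non-reference")
})

test_that("write_pangenome emits the full file set with 0-based half-open coordinates", {
  pg <- generate_pangenome(pangenome_config(n_triads = 4, n_cultivars = 3,
                                            seed = 5))
  d <- withr::local_tempdir()
  paths <- write_pangenome(pg, d)
  expect_length(paths, 3 * 2 + 4)   # per-cultivar FASTAs + 4 tables
  expect_true(all(file.exists(paths)))
  # FASTA round trip
  rt <- read_fasta(file.path(d, "ref.transcripts.fasta"))
  expect_identical(rt, transcripts(pg, "ref"))
  # coordinates: end - start equals CDS length
  g <- read_tsv(file.path(d, "genes.tsv"))
  cds_len <- nchar(pg$genes$cds[match(g$gene_id, pg$genes$gene_id)])
  expect_identical(g$end - g$start, cds_len)
})
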