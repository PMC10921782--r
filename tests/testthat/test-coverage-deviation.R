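mk_counts <- function(mat, window_size = 1000) {
  # rows = lines, cols = windows on one chromosome
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i)
    data.frame(line = rownames(mat)[i], chrom = "chr1",
               start = (seq_len(ncol(mat)) - 1) * window_size,
               end = seq_len(ncol(mat)) * window_size,
               count = mat[i, ])))
}

test_that("normalisation divides by line totals and cancels depth scaling", {
  m <- rbind(L1 = c(0, 100), L2 = c(50, 50))
  C <- normalize_counts(mk_counts(m))
  expect_equal(unname(C["L1", ]), c(0, 1))
  expect_equal(unname(C["L2", ]), c(0.5, 0.5))
  expect_equal(normalize_counts(mk_counts(m * 3)), C,
               ignore_attr = TRUE)
  m0 <- rbind(L1 = c(0, 0), L2 = c(1, 1))
  expect_error(normalize_counts(mk_counts(m0)), "L1")
})

test_that("the deviation statistic reproduces the hand-computed example", {
  # line L: window 1 empty, windows 2-10 at 100; lines M, N flat at 100
  m <- rbind(L = c(0, rep(100, 9)),
             M = rep(100, 10),
             N = rep(100, 10))
  dv <- coverage_deviation(mk_counts(m))
  expect_equal(unname(dv$d["L", ]), c(0, rep(1, 9)))
  expect_equal(unname(dv$d["M", ]), rep(1, 10))
  expect_equal(unname(dv$d["N", ]), rep(1, 10))
  # identical matrices: d = 1 everywhere
  m2 <- rbind(A = 1:10 * 10, B = 1:10 * 10, C = 1:10 * 10)
  expect_true(all(coverage_deviation(mk_counts(m2))$d == 1))
  expect_error(coverage_deviation(mk_counts(m[1:2, ])), "3 lines")
})

test_that("d is invariant to per-line depth scaling and shared per-window effects", {
  set.seed(50)
  m <- matrix(rpois(5 * 40, 200), nrow = 5,
              dimnames = list(paste0("L", 1:5), NULL))
  d0 <- coverage_deviation(mk_counts(m))$d
  m_scaled <- m
  m_scaled[2, ] <- m[2, ] * 3   # uniform depth scaling of one line
  expect_equal(coverage_deviation(mk_counts(m_scaled))$d, d0,
               tolerance = 1e-12, ignore_attr = TRUE)
  # per-window mappability effect shared by all lines, with line totals
  # held at the run's mapped-read count (totals are an external input, not
  # the window sum)
  weights <- rep(c(1, 2, 5), length.out = 40)
  m_win <- sweep(m, 2, weights, `*`)
  tot <- rowSums(m)
  expect_equal(coverage_deviation(mk_counts(m_win), totals = tot)$d,
               coverage_deviation(mk_counts(m), totals = tot)$d,
               tolerance = 1e-12, ignore_attr = TRUE)
  # median of each line's d over included windows is exactly 1
  expect_true(all(apply(d0, 1, median, na.rm = TRUE) == 1))
})

test_that("zero-median windows are excluded and reported", {
  m <- rbind(L1 = c(0, 10, 10, 10), L2 = c(0, 10, 10, 10),
             L3 = c(0, 10, 10, 10))
  dv <- coverage_deviation(mk_counts(m))
  expect_length(dv$excluded_windows, 1)
  expect_true(all(is.na(dv$d[, 1])))
  expect_true(all(dv$d[, -1] == 1))
})

test_that("MAD flagging matches an independent z-score oracle and handles degeneracy", {
  set.seed(51)
  base <- rpois(990, 400)
  m <- rbind(L = c(rep(0, 10), base),
             M = c(rpois(10, 400), base),
             N = c(rpois(10, 400), rpois(990, 400)))
  dv <- coverage_deviation(mk_counts(m))
  # lines sharing the same background profile can have zero MAD; harmless
  fl <- suppressWarnings(flag_outliers(dv, prob = 0.99))
  expect_true(all(fl["L", 1:10] == "below"))
  # oracle: recompute z for line L from its d vector
  dL <- dv$d["L", ]
  zo <- (dL - median(dL)) / (1.4826 * median(abs(dL - median(dL))))
  expect_equal(unname(attr(fl, "z")["L", ]), unname(zo), tolerance = 1e-12)
  expect_true(all(zo[1:10] < -qnorm(0.99)))
  # constant d: MAD zero, no flags, warning
  m2 <- rbind(A = rep(7, 6), B = rep(7, 6), C = rep(7, 6))
  dv2 <- coverage_deviation(mk_counts(m2))
  w <- capture_warnings(fl2 <- flag_outliers(dv2))
  expect_length(w, 3)            # one per degenerate line
  expect_match(w, "MAD", all = TRUE)
  expect_true(all(fl2 == "none"))
})

test_that("false-flag rate on event-free Poisson noise sits near the two-sided nominal rate", {
  wc <- simulate_window_counts(c(chr1 = 750000), 40, window_size = 5000,
                               depth = 200, seed = 5)
  fl <- flag_outliers(coverage_deviation(wc), prob = 0.99)
  rate <- mean(fl != "none")
  # nominal two-sided rate 2%; estimation noise in the median profile and
  # epsilon inflates the tails slightly
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.045)
})

test_that("flagged runs merge into blocks with minimum-span filtering", {
  windows <- data.frame(chrom = rep(c("chr1", "chr2"), c(10, 5)),
                        start = c(0:9, 0:4) * 1000,
                        end = c(1:10, 1:5) * 1000)
  fl <- matrix("none", 2, 15,
               dimnames = list(c("L1", "L2"), NULL))
  fl["L1", 3:7] <- "below"
  fl["L1", 12] <- "below"     # isolated, on chr2
  fl["L2", 14:15] <- "below"  # spans the chr2 end
  attr(fl, "windows") <- windows
  blocks <- merge_flagged_blocks(fl, min_windows = 2)
  expect_equal(nrow(blocks), 2)
  b1 <- blocks[blocks$line == "L1", ]
  expect_equal(c(b1$chrom, b1$start, b1$end, b1$n_windows),
               c("chr1", "2000", "7000", "5"))
  b2 <- blocks[blocks$line == "L2", ]
  expect_equal(c(b2$start, b2$end), c(3000, 5000))
  # deletion among otherwise identical lines is always fully recovered
  # (MAD flagging at prob 0.99 may add small noise blocks elsewhere)
  set.seed(52)
  m <- matrix(rpois(6 * 60, 300), nrow = 6,
              dimnames = list(paste0("L", 1:6), NULL))
  m[4, 21:30] <- 0
  fl3 <- flag_outliers(coverage_deviation(mk_counts(m)))
  expect_true(all(fl3["L4", 21:30] == "below"))
  blocks3 <- merge_flagged_blocks(fl3)
  del <- blocks3[blocks3$line == "L4" & blocks3$n_windows >= 5, ]
  expect_equal(nrow(del), 1)
  expect_equal(c(del$start, del$end), c(20000, 30000))
})

test_that("genes in recurrently flagged windows are found with enrichment fractions", {
  windows <- data.frame(chrom = "chr1", start = 0:9 * 1000,
                        end = 1:10 * 1000)
  fl <- matrix("none", 40, 10,
               dimnames = list(sprintf("L%02d", 1:40), NULL))
  fl[1:32, 4:5] <- "below"   # flagged in 32 of 40 lines
  fl[1:10, 8] <- "below"     # only 10 lines: not recurrent enough
  attr(fl, "windows") <- windows
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      start = 0:9 * 1000 + 500)
  res <- genes_in_divergent_windows(genes, fl, min_lines = 30,
                                    query = c("g4", "g5", "g9"))
  expect_setequal(res$genes, c("g4", "g5"))
  expect_equal(res$query_fraction, 2 / 3)
  expect_equal(res$genome_fraction, 0.2)
  # no flags anywhere: empty set, zero fractions
  fl0 <- matrix("none", 40, 10, dimnames = dimnames(fl))
  attr(fl0, "windows") <- windows
  res0 <- genes_in_divergent_windows(genes, fl0, query = "g1")
  expect_length(res0$genes, 0)
  expect_equal(res0$query_fraction, 0)
  # saturation: all query genes inside a universal block
  fl1 <- fl0; fl1[, ] <- "below"
  attr(fl1, "windows") <- windows
  res1 <- genes_in_divergent_windows(genes, fl1, query = genes$gene_id)
  expect_equal(res1$query_fraction, 1)
})
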