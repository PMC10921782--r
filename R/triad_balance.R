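#' Ideal homoeologue-balance category table
#'
#' The seven canonical triad expression categories and their ideal
#' normalised (A, B, D) read-count vectors. The balanced ideal is
#' (0.33, 0.33, 0.33) exactly as conventionally printed -- not (1/3, 1/3,
#' 1/3); the 0.0033 shortfall is preserved deliberately for fidelity to the
#' published category table.
#'
#' @return data frame `category`, `A`, `B`, `D` in the fixed tie-break
#'   order: Balanced, then suppressed A/B/D, then dominant A/B/D.
#' @export
ideal_categories <- function() {
  data.frame(
    category = c("Balanced", "A suppressed", "B suppressed", "D suppressed",
                 "A dominant", "B dominant", "D dominant"),
    A = c(0.33, 0, 0.5, 0.5, 1, 0, 0),
    B = c(0.33, 0.5, 0, 0.5, 0, 1, 0),
    D = c(0.33, 0.5, 0.5, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
}

#' Normalise triad read counts
#'
#' Each homoeologue's count divided by the triad total; a zero-total triad
#' cannot be normalised and is flagged excluded (`NA`s).
#'
#' @param A,B,D non-negative read counts (vectors of equal length).
#' @return data frame `a`, `b`, `d`, `excluded`.
#' @export
normalize_triad <- function(A, B, D) {
  stopifnot(all(A >= 0), all(B >= 0), all(D >= 0),
            length(A) == length(B), length(B) == length(D))
  tot <- A + B + D
  excluded <- tot == 0
  tot[excluded] <- NA_real_
  data.frame(a = A / tot, b = B / tot, d = D / tot, excluded = excluded)
}

#' Classify normalised triads by nearest ideal category
#'
#' Euclidean distance from the normalised (a, b, d) vector to each of the
#' seven ideal vectors; the category at minimal distance is assigned. Ties
#' are broken by the fixed order of [ideal_categories()] and reported via
#' the `tie` column.
#'
#' @param normalized data frame with columns `a`, `b`, `d` (rows with `NA`
#'   are left unclassified), or a numeric vector of length 3.
#' @param ideals category table, by default [ideal_categories()].
#' @return data frame `category` (factor), `min_distance`, `tie`, plus one
#'   distance column per category (`dist_<category>`).
#' @export
classify_triad <- function(normalized, ideals = ideal_categories()) {
  if (is.numeric(normalized) && length(normalized) == 3)
    normalized <- data.frame(a = normalized[1], b = normalized[2],
                             d = normalized[3])
  m <- as.matrix(normalized[, c("a", "b", "d")])
  im <- as.matrix(ideals[, c("A", "B", "D")])
  d2 <- outer(rowSums(m^2), rep(1, nrow(im))) -
    2 * m %*% t(im) + outer(rep(1, nrow(m)), rowSums(im^2))
  dist <- sqrt(pmax(d2, 0))
  colnames(dist) <- ideals$category
  na <- !stats::complete.cases(m)
  safe <- dist
  safe[na, ] <- 0
  best <- apply(safe, 1, which.min)            # first minimum = fixed order
  mind <- dist[cbind(seq_len(nrow(dist)), best)]
  tie <- rowSums(abs(dist - mind) < 1e-12) > 1
  out <- data.frame(category = factor(ifelse(na, NA,
                                             ideals$category[best]),
                                      levels = ideals$category),
                    min_distance = ifelse(na, NA, mind),
                    tie = ifelse(na, NA, tie))
  dd <- as.data.frame(dist)
  names(dd) <- paste0("dist_", gsub(" ", "_", ideals$category))
  cbind(out, dd)
}

#' Triad balance from gene-level counts
#'
#' Convenience wrapper: looks up the three homoeologue counts of each triad,
#' normalises, classifies, and carries ternary plotting coordinates.
#'
#' @param gene_counts named numeric vector (or `gene_quant` data frame) of
#'   gene counts.
#' @param triads data frame `triad_id`, `gene_A`, `gene_B`, `gene_D`.
#' @param keep_triads optional triad ids to retain (e.g. triads whose three
#'   homoeologues were all simulated in the read-source cultivar); default
#'   all triads whose three genes are present in `gene_counts`.
#' @return data frame of class `triad_balance`: `triad_id`, raw counts,
#'   `a`, `b`, `d`, `category`, `min_distance`, `excluded`, and ternary
#'   coordinates `tern_x`, `tern_y`.
#' @export
triad_balance <- function(gene_counts, triads, keep_triads = NULL) {
  if (is.data.frame(gene_counts))
    gene_counts <- setNames(gene_counts$est_count, gene_counts$gene_id)
  tr <- triads
  if (!is.null(keep_triads)) tr <- tr[tr$triad_id %in% keep_triads, ]
  have <- tr$gene_A %in% names(gene_counts) &
    tr$gene_B %in% names(gene_counts) & tr$gene_D %in% names(gene_counts)
  tr <- tr[have, , drop = FALSE]
  A <- unname(gene_counts[tr$gene_A])
  B <- unname(gene_counts[tr$gene_B])
  D <- unname(gene_counts[tr$gene_D])
  nm <- normalize_triad(A, B, D)
  cl <- classify_triad(nm)
  out <- data.frame(triad_id = tr$triad_id, A = A, B = B, D = D,
                    a = nm$a, b = nm$b, d = nm$d,
                    category = cl$category,
                    min_distance = cl$min_distance,
                    excluded = nm$excluded,
                    tern_x = nm$b + nm$d / 2,    # ternary projection
                    tern_y = nm$d * sqrt(3) / 2,
                    stringsAsFactors = FALSE)
  class(out) <- c("triad_balance", "data.frame")
  out
}

#' Category proportions across classified triads
#'
#' @param balances a [triad_balance()] result (or any data frame with a
#'   `category` column and optional `excluded`).
#' @return data frame `category`, `n`, `percent`; percentages are over
#'   classified (non-excluded) triads and sum to 100. Excluded triads are
#'   reported in the `n_excluded` attribute.
#' @export
category_summary <- function(balances) {
  excl <- if ("excluded" %in% names(balances)) balances$excluded else
    is.na(balances$category)
  cl <- balances$category[!excl]
  stopifnot(length(cl) > 0)
  tab <- table(cl)
  out <- data.frame(category = names(tab), n = as.numeric(tab),
                    percent = 100 * as.numeric(tab) / length(cl),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(excl)
  out
}

#' @method plot triad_balance
#' @export
plot.triad_balance <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.08, 0.95),
                 axes = FALSE, xlab = "", ylab = "", asp = 1, ...)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  graphics::text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.05),
                 c("A", "B", "D"))
  graphics::points(x$tern_x, x$tern_y, pch = 16, cex = 0.5,
                   col = as.integer(x$category))
  invisible(x)
}

#' Minimum Spearman correlation between homoeologue pairs
#'
#' For each complete triad, Spearman's rank correlation (average ranks for
#' ties) is computed across samples for the AB, AD and BD homoeologue pairs
#' and the lowest of the three is returned -- the conservative measure of
#' within-triad expression coordination. A zero-variance expression vector
#' leaves its pairs undefined; those pairs are dropped from the minimum, and
#' a triad with all three pairs undefined yields `NA`.
#'
#' @param expression_matrix numeric matrix, genes x samples (>= 3 samples),
#'   with gene ids as row names.
#' @param triads data frame `triad_id`, `gene_A`, `gene_B`, `gene_D`;
#'   triads with any homoeologue absent from the matrix are excluded.
#' @return data frame `triad_id`, `scc_AB`, `scc_AD`, `scc_BD`, `min_scc`.
#' @export
homoeologue_scc <- function(expression_matrix, triads) {
  stopifnot(is.matrix(expression_matrix), ncol(expression_matrix) >= 3,
            !is.null(rownames(expression_matrix)))
  keep <- triads$gene_A %in% rownames(expression_matrix) &
    triads$gene_B %in% rownames(expression_matrix) &
    triads$gene_D %in% rownames(expression_matrix)
  tr <- triads[keep, , drop = FALSE]
  scc <- function(g1, g2) {
    x <- expression_matrix[g1, ]; y <- expression_matrix[g2, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }
  if (nrow(tr) == 0) {
    return(data.frame(triad_id = character(), scc_AB = numeric(),
                      scc_AD = numeric(), scc_BD = numeric(),
                      min_scc = numeric(), stringsAsFactors = FALSE))
  }
  ab <- vapply(seq_len(nrow(tr)), function(i) scc(tr$gene_A[i], tr$gene_B[i]), 0)
  ad <- vapply(seq_len(nrow(tr)), function(i) scc(tr$gene_A[i], tr$gene_D[i]), 0)
  bd <- vapply(seq_len(nrow(tr)), function(i) scc(tr$gene_B[i], tr$gene_D[i]), 0)
  mn <- apply(cbind(ab, ad, bd), 1, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  data.frame(triad_id = tr$triad_id, scc_AB = ab, scc_AD = ad,
             scc_BD = bd, min_scc = unname(mn), stringsAsFactors = FALSE)
}
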