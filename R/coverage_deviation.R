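#' Depth-normalise a window count matrix
#'
#' Divides each line's window counts by its total mapped reads, removing
#' per-line sequencing-depth differences.
#'
#' @param counts a `window_counts` data frame (`line`, `chrom`, `start`,
#'   `end`, `count`) or a numeric matrix lines x windows.
#' @param totals optional named per-line totals; default the line's sum of
#'   window counts.
#' @return numeric matrix lines x windows of normalised counts, with window
#'   metadata in the `windows` attribute when available.
#' @export
normalize_counts <- function(counts, totals = NULL) {
  wm <- as_window_matrix(counts)
  m <- wm$m
  if (is.null(totals)) totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero))
    stop("line(s) with zero total mapped reads: ",
         paste(rownames(m)[zero], collapse = ", "))
  out <- m / totals[rownames(m)]
  attr(out, "windows") <- wm$windows
  out
}

# accept long-format window_counts or a plain matrix
as_window_matrix <- function(counts) {
  if (is.matrix(counts))
    return(list(m = counts, windows = attr(counts, "windows")))
  stopifnot(all(c("line", "chrom", "start", "end", "count") %in%
                  names(counts)))
  wins <- unique(counts[, c("chrom", "start", "end")])
  wins <- wins[order(wins$chrom, wins$start), ]
  wkey <- paste0(wins$chrom, ":", wins$start, "-", wins$end)
  lines <- unique(counts$line)
  m <- matrix(NA_real_, length(lines), nrow(wins),
              dimnames = list(lines, wkey))
  m[cbind(match(counts$line, lines),
          match(paste0(counts$chrom, ":", counts$start, "-", counts$end),
                wkey))] <- counts$count
  if (anyNA(m)) stop("window count matrix is ragged across lines")
  rownames(wins) <- NULL
  list(m = m, windows = wins)
}

#' Mapping coverage deviation across lines
#'
#' For each line and window the deviation statistic is
#' `d_i = C_i / (m_i * eps)`, where `C_i` is the line's depth-normalised
#' count in window i, `m_i` is the across-line median of `C_i` for that
#' window, and `eps` is the line's median of the raw ratios
#' `r_i = C_i / m_i` across its genome -- so the median of each line's `d`
#' over included windows is exactly 1. Windows whose across-line median is
#' zero have no defined ratio; they are excluded from `eps` and reported
#' (`d` is `NA` there). `d` is invariant to per-line uniform depth scaling
#' and to per-window effects shared by all lines: values well below 1 mark
#' divergent (introgressed) or deleted material in that line.
#'
#' @param counts a `window_counts` data frame or lines x windows matrix of
#'   raw counts (>= 3 lines).
#' @param totals optional per-line mapped-read totals.
#' @return an object of class `coverage_deviation`: a list with matrices
#'   `C` (normalised counts), `r`, `d`, vectors `median_profile` (`m`),
#'   `epsilon` per line, `excluded_windows` (zero-median window names), and
#'   the window metadata.
#' @export
coverage_deviation <- function(counts, totals = NULL) {
  C <- normalize_counts(counts, totals)
  if (nrow(C) < 3)
    stop("need at least 3 lines for a meaningful median profile")
  m <- apply(C, 2, median)
  included <- m > 0
  if (!any(included))
    stop("all windows have zero across-line median coverage")
  r <- sweep(C, 2, m, `/`)
  r[, !included] <- NA_real_
  eps <- apply(r[, included, drop = FALSE], 1, median)
  if (any(eps == 0))
    stop("line(s) with zero median ratio: ",
         paste(rownames(C)[eps == 0], collapse = ", "))
  d <- r / eps
  structure(list(C = C, r = r, d = d, median_profile = m, epsilon = eps,
                 excluded_windows = colnames(C)[!included],
                 windows = attr(C, "windows")),
            class = "coverage_deviation")
}

#' @export
print.coverage_deviation <- function(x, ...) {
  cat("coverage_deviation:", nrow(x$d), "lines x", ncol(x$d), "windows;",
      length(x$excluded_windows), "window(s) excluded (zero median)\n")
  invisible(x)
}

#' Flag outlying deviation values by the MAD criterion
#'
#' Per line, across its own genome: `z_i = (d_i - median(d)) /
#' (1.4826 * MAD(d))`; a window is flagged `below` when
#' `z_i < -qnorm(prob)` and `above` when `z_i > qnorm(prob)` (two-sided,
#' with direction labels; filter on `below` for introgression/deletion
#' scanning). A line whose `d` values have zero MAD yields no flags, with a
#' warning.
#'
#' @param deviation a [coverage_deviation()] result.
#' @param prob flagging probability (default 0.99, i.e. |z| > 2.3263).
#' @return character matrix lines x windows with values `"none"`,
#'   `"below"`, `"above"` (`NA` for excluded windows), with the `z` matrix
#'   and window metadata as attributes.
#' @export
flag_outliers <- function(deviation, prob = 0.99) {
  stopifnot(inherits(deviation, "coverage_deviation"),
            prob > 0.5, prob < 1)
  d <- deviation$d
  if (ncol(d) < 3) stop("need at least 3 windows per line")
  thr <- qnorm(prob)
  z <- d
  flags <- matrix(NA_character_, nrow(d), ncol(d), dimnames = dimnames(d))
  for (ln in rownames(d)) {
    v <- d[ln, ]
    ok <- !is.na(v)
    md <- median(v[ok])
    s <- 1.4826 * median(abs(v[ok] - md))
    if (s == 0) {
      warning("line '", ln, "': MAD of d is zero; no flags assigned")
      z[ln, ok] <- 0
      flags[ln, ok] <- "none"
      next
    }
    z[ln, ok] <- (v[ok] - md) / s
    flags[ln, ok] <- ifelse(z[ln, ok] < -thr, "below",
                            ifelse(z[ln, ok] > thr, "above", "none"))
  }
  attr(flags, "z") <- z
  attr(flags, "windows") <- deviation$windows
  attr(flags, "prob") <- prob
  flags
}

#' Merge runs of below-flagged windows into candidate blocks
#'
#' Consecutive `below`-flagged windows on one chromosome are merged;
#' blocks spanning fewer than `min_windows` windows are dropped. These are
#' the candidate introgression/deletion intervals of a line.
#'
#' @param flags the [flag_outliers()] matrix (or one line's character
#'   vector with window metadata attached).
#' @param min_windows minimum run length to keep (default 2).
#' @return BED-like data frame `line`, `chrom`, `start`, `end`,
#'   `n_windows`.
#' @export
merge_flagged_blocks <- function(flags, min_windows = 2) {
  windows <- attr(flags, "windows")
  if (is.null(windows)) stop("flags carry no window metadata")
  if (!is.matrix(flags))
    flags <- matrix(flags, 1, dimnames = list("line1", names(flags)))
  out <- list()
  for (ln in rownames(flags)) {
    below <- !is.na(flags[ln, ]) & flags[ln, ] == "below"
    for (ch in unique(windows$chrom)) {
      iw <- which(windows$chrom == ch)
      rl <- rle(below[iw])
      pos <- cumsum(c(1, rl$lengths))
      for (j in which(rl$values & rl$lengths >= min_windows)) {
        idx <- iw[pos[j]:(pos[j + 1] - 1)]
        out[[length(out) + 1]] <- data.frame(
          line = ln, chrom = ch, start = min(windows$start[idx]),
          end = max(windows$end[idx]), n_windows = length(idx),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(line = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer()))
  do.call(rbind, out)
}

#' Genes in windows flagged divergent across many lines
#'
#' Selects windows below-flagged in at least `min_lines` lines, returns the
#' genes whose start coordinate falls in them, and optionally contrasts a
#' query gene list's overlap fraction with the genome-wide fraction.
#'
#' @param gene_coords data frame `gene_id`, `chrom`, `start`.
#' @param flags the [flag_outliers()] matrix across lines.
#' @param min_lines minimum number of below-flagged lines for a window to
#'   count (field convention: 30 of ~190 accessions).
#' @param query optional character vector of gene ids of interest.
#' @return a list: `windows` (selected window metadata), `genes` (ids
#'   inside), and with a query, `query_fraction` and `genome_fraction`.
#' @export
genes_in_divergent_windows <- function(gene_coords, flags, min_lines = 30,
                                       query = NULL) {
  windows <- attr(flags, "windows")
  if (is.null(windows)) stop("flags carry no window metadata")
  n_below <- colSums(!is.na(flags) & flags == "below")
  sel <- n_below >= min_lines
  wsel <- windows[sel, , drop = FALSE]
  inside <- rep(FALSE, nrow(gene_coords))
  for (i in seq_len(nrow(wsel))) {
    inside <- inside | (gene_coords$chrom == wsel$chrom[i] &
                          gene_coords$start >= wsel$start[i] &
                          gene_coords$start < wsel$end[i])
  }
  res <- list(windows = wsel, genes = gene_coords$gene_id[inside])
  if (!is.null(query)) {
    res$query_fraction <- if (length(query))
      mean(query %in% res$genes) else 0
    res$genome_fraction <- mean(inside)
  }
  res
}
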