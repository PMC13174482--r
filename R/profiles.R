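# Aggregate signal profiles: per-bp coverage from cut sites, anchor-centered
# binned matrices (peak center +/- 2 kb, TSS +/- 2 kb), and matrix
# comparison summaries.

#' Per-bp coverage track from cut-site intervals
#'
#' `coverage[x]` is the number of cut-site intervals containing bp `x`,
#' stored run-length encoded per chromosome.
#'
#' @param cuts data.frame of cut-site intervals.
#' @param sizes named chromosome lengths (every chromosome in `sizes` gets a
#'   track, so anchors on cut-free chromosomes still profile as zero).
#' @return a `coverage_track`: list with `cov` (list of Rle per chromosome)
#'   and `sizes`.
#' @export
coverage_track <- function(cuts, sizes) {
  .check_sizes(sizes)
  .check_intervals(cuts, "cuts")
  .check_chroms_known(cuts$chrom, sizes, "cuts")
  if (nrow(cuts) && (any(cuts$start < 0) || any(cuts$end > sizes[cuts$chrom]))) {
    stop("cut sites outside chromosome bounds")
  }
  cov <- lapply(names(sizes), function(chr) {
    d <- cuts[cuts$chrom == chr, , drop = FALSE]
    IRanges::coverage(IRanges::IRanges(d$start + 1L, d$end),
                      width = as.integer(sizes[[chr]]))
  })
  names(cov) <- names(sizes)
  structure(list(cov = cov, sizes = sizes), class = "coverage_track")
}

#' Convert a coverage track to a bedGraph data.frame
#'
#' Zero-coverage runs are omitted.
#'
#' @param track a `coverage_track`.
#' @return data.frame `chrom, start, end, value`.
#' @export
track_to_bedgraph <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  pieces <- lapply(names(track$cov), function(chr) {
    r <- track$cov[[chr]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    e <- cumsum(l)
    s <- e - l
    keep <- v != 0
    data.frame(chrom = chr, start = as.integer(s[keep]),
               end = as.integer(e[keep]), value = as.numeric(v[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Build a coverage track from a bedGraph data.frame
#'
#' @param df data.frame `chrom, start, end, value` (integer values).
#' @param sizes named chromosome lengths.
#' @return a `coverage_track`.
#' @export
bedgraph_to_track <- function(df, sizes) {
  .check_sizes(sizes)
  .check_intervals(df, "bedGraph")
  .check_chroms_known(df$chrom, sizes, "bedGraph")
  cov <- lapply(names(sizes), function(chr) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    len <- as.integer(sizes[[chr]])
    if (!nrow(d)) return(S4Vectors::Rle(0, len))
    if (any(d$start[-1L] < d$end[-nrow(d)])) {
      stop("bedGraph records overlap on ", chr)
    }
    # interleave zero-coverage gaps with the recorded runs, plus a tail gap
    gap <- d$start - c(0L, d$end[-nrow(d)])
    vals <- c(rbind(0, d$value), 0)
    lens <- c(rbind(gap, d$end - d$start), len - d$end[nrow(d)])
    keep <- lens > 0
    S4Vectors::Rle(vals[keep], lens[keep])
  })
  names(cov) <- names(sizes)
  structure(list(cov = cov, sizes = sizes), class = "coverage_track")
}

#' Anchor-centered binned signal matrix
#'
#' Row i, bin j holds the mean per-bp coverage over
#' `[anchor_i - flank + (j - 1) * bin_size, anchor_i - flank + j * bin_size)`.
#' Bins clipped by a chromosome edge average over the available bp; anchors
#' lying outside their chromosome give a row of `NA` with a warning. With
#' `strand_aware = TRUE`, rows anchored on the minus strand are reversed so
#' transcription reads left to right.
#'
#' @param track a `coverage_track`.
#' @param anchors data.frame with `chrom`, `pos` (bp) and optional `strand`.
#' @param flank bp each side (default 2000); must be divisible by
#'   `bin_size`.
#' @param bin_size bp per bin (default 10).
#' @param strand_aware reverse minus-strand rows (default TRUE).
#' @return a `profile_matrix`: list with `matrix` (anchors x bins),
#'   `mean_profile`, `anchors`, `flank`, `bin_size`.
#' @export
profile_matrix <- function(track, anchors, flank = 2000, bin_size = 10,
                           strand_aware = TRUE) {
  stopifnot(inherits(track, "coverage_track"), is.data.frame(anchors),
            all(c("chrom", "pos") %in% names(anchors)))
  if (flank %% bin_size != 0) stop("flank must be divisible by bin_size")
  .check_chroms_known(anchors$chrom, track$sizes, "anchors")
  nb <- as.integer(2 * flank / bin_size)
  n <- nrow(anchors)
  mat <- matrix(NA_real_, nrow = n, ncol = nb)
  strand <- anchors$strand
  if (is.null(strand)) strand <- rep(".", n)
  outside <- anchors$pos < 0 | anchors$pos >= track$sizes[anchors$chrom]
  if (any(outside)) warning(sum(outside), " anchor(s) outside chromosome")
  offsets <- seq.int(0L, nb - 1L) * bin_size
  for (chr in unique(anchors$chrom)) {
    rows <- which(anchors$chrom == chr & !outside)
    if (!length(rows)) next
    r <- track$cov[[chr]]
    len <- as.integer(track$sizes[[chr]])
    s0 <- rep(anchors$pos[rows] - flank, each = nb) +
      rep(offsets, times = length(rows))
    e0 <- s0 + bin_size
    s <- pmax(0L, as.integer(s0))
    e <- pmin(len, as.integer(e0))
    ok <- e > s
    means <- rep(NA_real_, length(s0))
    if (any(ok)) {
      v <- IRanges::Views(r, IRanges::IRanges(s[ok] + 1L, e[ok]))
      means[ok] <- IRanges::viewMeans(v)
    }
    mat[rows, ] <- matrix(means, ncol = nb, byrow = TRUE)
  }
  if (strand_aware) {
    rev_rows <- which(strand == "-")
    if (length(rev_rows)) mat[rev_rows, ] <- mat[rev_rows, nb:1, drop = FALSE]
  }
  structure(list(matrix = mat,
                 mean_profile = colMeans(mat, na.rm = TRUE),
                 anchors = anchors, flank = flank, bin_size = bin_size,
                 strand_aware = strand_aware),
            class = "profile_matrix")
}

#' Compare two profile matrices
#'
#' @param a,b `profile_matrix` objects of identical shape.
#' @return list with `difference` (b - a, elementwise), `mean_difference`
#'   (per-bin), and per-matrix summaries `center_a`, `center_b` (mean signal
#'   in the central bin), `auc_a`, `auc_b` (area under the mean profile, bp
#'   weighted) and `center_ratio` (b over a).
#' @export
mean_profile_compare <- function(a, b) {
  stopifnot(inherits(a, "profile_matrix"), inherits(b, "profile_matrix"))
  if (!all(dim(a$matrix) == dim(b$matrix))) stop("profile matrix shape mismatch")
  nb <- ncol(a$matrix)
  center <- c(nb %/% 2L, nb %/% 2L + 1L)  # the two bins flanking the anchor
  center_a <- mean(a$mean_profile[center])
  center_b <- mean(b$mean_profile[center])
  list(difference = b$matrix - a$matrix,
       mean_difference = b$mean_profile - a$mean_profile,
       center_a = center_a, center_b = center_b,
       center_ratio = if (center_a > 0) center_b / center_a else NA_real_,
       auc_a = sum(a$mean_profile) * a$bin_size,
       auc_b = sum(b$mean_profile) * b$bin_size)
}

#' Sort profile rows by mean signal for heatmap export
#'
#' Stable descending sort by row mean.
#'
#' @param pm a `profile_matrix`.
#' @return the `profile_matrix` with rows (and anchors) reordered.
#' @export
sort_profile_rows <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  o <- order(-rowMeans(pm$matrix, na.rm = TRUE), method = "radix")
  pm$matrix <- pm$matrix[o, , drop = FALSE]
  pm$anchors <- pm$anchors[o, , drop = FALSE]
  pm$mean_profile <- colMeans(pm$matrix, na.rm = TRUE)
  pm
}

#' Plot the mean profile of one or more profile matrices
#'
#' @param x a `profile_matrix`.
#' @param y optional second `profile_matrix` drawn for comparison.
#' @param ... passed to [graphics::plot()].
#' @export
plot.profile_matrix <- function(x, y = NULL, ...) {
  pos <- seq(-x$flank + x$bin_size / 2, x$flank - x$bin_size / 2,
             by = x$bin_size)
  graphics::plot(pos, x$mean_profile, type = "l",
                 xlab = "distance from anchor (bp)",
                 ylab = "mean coverage", ...)
  if (!is.null(y)) {
    graphics::lines(pos, y$mean_profile, lty = 2)
  }
  graphics::abline(v = 0, col = "grey70", lty = 3)
  invisible(x)
}
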