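# Differential accessibility over the merged peak universe: library
# down-sampling, Tn5 cut-site extraction, per-region counting, per-sample
# depth normalization, and a two-sample t test on log2 signal with BH
# adjustment.

#' Down-sample fragments to a fixed count
#'
#' Uniform random subset of size `min(n, nrow(fragments))` without
#' replacement, deterministic given `seed`. Relative input order of the
#' retained fragments is preserved.
#'
#' @param fragments data.frame of intervals.
#' @param n target count (>= 0).
#' @param seed integer seed.
#' @return subset of `fragments`.
#' @export
downsample_fragments <- function(fragments, n, seed = 1L) {
  stopifnot(is.data.frame(fragments))
  if (n < 0) stop("n must be >= 0")
  total <- nrow(fragments)
  if (n >= total) return(fragments)
  keep <- with_seed(seed, sort(sample.int(total, n)))
  fragments[keep, , drop = FALSE]
}

#' Extract Tn5 cut-site intervals from fragments or reads
#'
#' The accessibility signal is the first `cut_width` bp at each read 5' end:
#' a plus-strand read contributes `[start, start + cut_width)`, a
#' minus-strand read `[end - cut_width, end)`, and a full fragment (strand
#' `"."` or missing) contributes both ends. Intervals are clipped to the
#' chromosome when sizes are given.
#'
#' @param fragments data.frame with `chrom, start, end` and optional
#'   `strand` (`"+"`, `"-"`, or `"."` for a full fragment).
#' @param cut_width bp per cut site (default 9).
#' @param sizes optional named chromosome lengths for clipping.
#' @return data.frame `chrom, start, end` of cut-site intervals.
#' @export
extract_cut_sites <- function(fragments, cut_width = 9, sizes = NULL) {
  if (cut_width < 1) stop("cut_width must be >= 1")
  .check_intervals(fragments, "fragments")
  .check_sizes(sizes)
  strand <- fragments$strand
  if (is.null(strand)) strand <- rep(".", nrow(fragments))
  strand[is.na(strand)] <- "."
  plus <- strand == "+"
  minus <- strand == "-"
  both <- !plus & !minus
  five <- data.frame(chrom = fragments$chrom[plus | both],
                     start = fragments$start[plus | both],
                     stringsAsFactors = FALSE)
  five$end <- five$start + as.integer(cut_width)
  three <- data.frame(chrom = fragments$chrom[minus | both],
                      end = fragments$end[minus | both],
                      stringsAsFactors = FALSE)
  three$start <- three$end - as.integer(cut_width)
  out <- rbind(five[, c("chrom", "start", "end")],
               three[, c("chrom", "start", "end")])
  out$start <- pmax(0L, out$start)
  if (!is.null(sizes)) {
    .check_chroms_known(out$chrom, sizes, "fragments")
    out$end <- pmin(as.integer(sizes[out$chrom]), out$end)
  }
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count cut sites over a disjoint region universe
#'
#' A cut site increments every region it overlaps by at least 1 bp (after
#' merging with a gap of at least `cut_width` this is at most one region).
#'
#' @param regions merged, disjoint interval data.frame.
#' @param cuts_by_sample named list of cut-site data.frames, one per sample.
#' @param conditions character vector of condition labels, parallel to
#'   `cuts_by_sample`.
#' @return a `region_signal` list: `regions`, integer `counts` matrix
#'   (regions x samples), `samples` data.frame (`sample, condition`),
#'   `library_sizes` (total cut sites per sample) and `normalized` (counts
#'   scaled per sample to 10 million in-region counts).
#' @export
count_in_regions <- function(regions, cuts_by_sample, conditions) {
  .check_intervals(regions, "regions")
  stopifnot(is.list(cuts_by_sample), length(cuts_by_sample) >= 1,
            length(conditions) == length(cuts_by_sample))
  if (nrow(regions) > 1L) {
    srt <- .sort_intervals(regions)
    same <- srt$chrom[-1L] == srt$chrom[-nrow(srt)]
    if (any(same & srt$start[-1L] < srt$end[-nrow(srt)])) {
      stop("regions must be disjoint (merge them first)")
    }
  }
  if (is.null(names(cuts_by_sample))) {
    names(cuts_by_sample) <- paste0("sample", seq_along(cuts_by_sample))
  }
  rgr <- .as_granges(regions)
  counts <- vapply(cuts_by_sample, function(cuts) {
    .check_intervals(cuts, "cut sites")
    if (!nrow(cuts)) return(integer(nrow(regions)))
    GenomicRanges::countOverlaps(rgr, .as_granges(cuts), minoverlap = 1L,
                                 ignore.strand = TRUE)
  }, integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(NULL, names(cuts_by_sample)))
  library_sizes <- vapply(cuts_by_sample, nrow, 1L)
  insum <- colSums(counts)
  scale <- ifelse(insum > 0, 1e7 / insum, 0)
  normalized <- sweep(counts, 2L, scale, `*`)
  structure(list(
    regions = regions,
    counts = counts,
    samples = data.frame(sample = names(cuts_by_sample),
                         condition = as.character(conditions),
                         stringsAsFactors = FALSE),
    library_sizes = library_sizes,
    normalized = normalized
  ), class = "region_signal")
}

#' Build a region signal object from an existing count matrix
#'
#' For counts quantified outside this package (or simulated directly).
#' Applies the same per-sample normalization as [count_in_regions()]:
#' counts scaled to 10 million in-region counts per sample.
#'
#' @param regions interval data.frame, one row per matrix row.
#' @param counts non-negative integer matrix, regions x samples.
#' @param conditions condition label per column.
#' @param library_sizes optional per-sample totals (defaults to the column
#'   sums).
#' @return a `region_signal` object.
#' @export
region_signal <- function(regions, counts, conditions,
                          library_sizes = colSums(counts)) {
  .check_intervals(regions, "regions")
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(regions),
            ncol(counts) == length(conditions),
            all(counts >= 0))
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  insum <- colSums(counts)
  scale <- ifelse(insum > 0, 1e7 / insum, 0)
  structure(list(
    regions = regions,
    counts = counts,
    samples = data.frame(sample = colnames(counts),
                         condition = as.character(conditions),
                         stringsAsFactors = FALSE),
    library_sizes = library_sizes,
    normalized = sweep(counts, 2L, scale, `*`)
  ), class = "region_signal")
}

# vectorized two-sample t (pooled variance) over rows of a matrix;
# cross-checked against stats::t.test(var.equal = TRUE) in the test suite.
# The pooled form is used because at 3 replicates per condition it holds its
# nominal size, where the Welch-Satterthwaite approximation is markedly
# conservative.
.t_rows <- function(y, ia, ib) {
  n1 <- length(ia); n2 <- length(ib)
  m1 <- rowMeans(y[, ia, drop = FALSE])
  m2 <- rowMeans(y[, ib, drop = FALSE])
  v1 <- rowSums((y[, ia, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((y[, ib, drop = FALSE] - m2)^2) / (n2 - 1)
  vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se2 <- vp * (1 / n1 + 1 / n2)
  diff <- m2 - m1
  t <- diff / sqrt(se2)
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  # zero-variance rows: identical values give p = 1 by convention, a
  # nonzero difference with no within-group spread is maximally significant
  degenerate <- se2 == 0
  p[degenerate & diff == 0] <- 1
  p[degenerate & diff != 0] <- 0
  list(diff = diff, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Test differential accessibility over a region universe
#'
#' Per region, `y = log2(normalized + 1)`; the log2 fold change is
#' `mean(y_treatment) - mean(y_reference)` and the p-value comes from a
#' two-sided pooled-variance t test on `y` (regions with identical values in both
#' groups get p = 1). P-values are BH-adjusted over all regions and each
#' region is classed `increased` / `decreased` / `unchanged` by
#' `adj_p < dar_adj_p` and `|log2fc| >= dar_abs_log2fc`.
#'
#' @param signal a `region_signal` from [count_in_regions()].
#' @param treatment,reference condition labels in `signal$samples$condition`.
#' @param params an [analysis_params()] list (uses `dar_adj_p`,
#'   `dar_abs_log2fc`).
#' @return a `dar_result` data.frame: `chrom, start, end, mean_reference,
#'   mean_treatment, log2fc, p, adj_p, class`.
#' @export
test_differential <- function(signal, treatment = "treated",
                              reference = "vehicle",
                              params = analysis_params()) {
  stopifnot(inherits(signal, "region_signal"))
  if (!nrow(signal$regions)) stop("empty region universe")
  cond <- signal$samples$condition
  ia <- which(cond == reference)
  ib <- which(cond == treatment)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("need >= 2 replicates per condition")
  }
  y <- log2(signal$normalized + 1)
  w <- .t_rows(y, ia, ib)
  adj <- bh_adjust(w$p)
  class <- rep("unchanged", nrow(y))
  sig <- adj < params$dar_adj_p & abs(w$diff) >= params$dar_abs_log2fc
  class[sig & w$diff > 0] <- "increased"
  class[sig & w$diff < 0] <- "decreased"
  out <- data.frame(
    chrom = signal$regions$chrom,
    start = signal$regions$start,
    end = signal$regions$end,
    mean_reference = rowMeans(y[, ia, drop = FALSE]),
    mean_treatment = rowMeans(y[, ib, drop = FALSE]),
    log2fc = w$diff,
    p = w$p,
    adj_p = adj,
    class = class,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("dar_result", "data.frame"),
            treatment = treatment, reference = reference,
            dar_adj_p = params$dar_adj_p,
            dar_abs_log2fc = params$dar_abs_log2fc)
}

#' @export
print.dar_result <- function(x, ...) {
  cat(sprintf(
    "Differential accessibility: %d regions (%s vs %s)\n",
    nrow(x), attr(x, "treatment"), attr(x, "reference")))
  cat(sprintf("  increased %d, decreased %d, unchanged %d (adj p < %g, |log2FC| >= %g)\n",
              sum(x$class == "increased"), sum(x$class == "decreased"),
              sum(x$class == "unchanged"),
              attr(x, "dar_adj_p"), attr(x, "dar_abs_log2fc")))
  invisible(x)
}

#' @export
summary.dar_result <- function(object, ...) {
  counts <- c(increased = sum(object$class == "increased"),
              decreased = sum(object$class == "decreased"),
              unchanged = sum(object$class == "unchanged"))
  list(counts = counts,
       thresholds = c(adj_p = attr(object, "dar_adj_p"),
                      abs_log2fc = attr(object, "dar_abs_log2fc")))
}

#' Volcano plot of a differential accessibility result
#'
#' @param x a `dar_result`.
#' @param y unused.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dar_result <- function(x, y, ...) {
  col <- c(increased = "firebrick", decreased = "steelblue",
           unchanged = "grey60")[x$class]
  graphics::plot(x$log2fc, -log10(pmax(x$adj_p, 1e-300)), col = col,
                 pch = 20, xlab = "log2 fold change",
                 ylab = "-log10 adjusted p", ...)
  graphics::abline(v = c(-1, 1) * attr(x, "dar_abs_log2fc"), lty = 2)
  graphics::abline(h = -log10(attr(x, "dar_adj_p")), lty = 2)
  invisible(x)
}
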