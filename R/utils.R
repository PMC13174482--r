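# internal helpers shared across modules

# round half up (the convention used for reported percentages; base round()
# is half-even)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, rounded half-up to two decimals
#'
#' Reporting helper used by the integration summaries: percentages are
#' rounded half-up (so 80.8485 prints as 80.85, never 80.84).
#'
#' @param n numerator count.
#' @param total denominator count; `total = 0` yields `NA`.
#' @param digits decimal places (default 2).
#' @return numeric percentage on the 0-100 scale.
#' @examples
#' pct(104503, 104503 + 24743)
#' @export
pct <- function(n, total, digits = 2) {
  ifelse(total == 0, NA_real_, round_half_up(100 * n / total, digits))
}

# run code with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- interval data.frame <-> GRanges conversion -----------------------------
# data.frames carry 0-based half-open coordinates; GRanges is 1-based closed.

.as_granges <- function(df, use_strand = FALSE) {
  strand <- if (use_strand && !is.null(df$strand)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

.check_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop(what, " data.frame needs columns chrom, start, end")
  }
  if (nrow(df) && any(df$end <= df$start)) {
    stop(what, ": end must be > start (0-based half-open)")
  }
  invisible(df)
}

.check_sizes <- function(sizes) {
  if (is.null(sizes)) return(invisible(NULL))
  if (is.null(names(sizes)) || anyDuplicated(names(sizes))) {
    stop("chromosome sizes must be a uniquely named vector")
  }
  if (any(sizes < 1)) stop("chromosome lengths must be >= 1")
  invisible(sizes)
}

.check_chroms_known <- function(chroms, sizes, where = "input") {
  if (is.null(sizes)) return(invisible(NULL))
  bad <- setdiff(unique(as.character(chroms)), names(sizes))
  if (length(bad)) {
    stop(where, ": chromosome(s) not in sizes: ", paste(bad, collapse = ", "))
  }
  invisible(NULL)
}

# stable sort of an interval data.frame by (chrom, start, end)
.sort_intervals <- function(df) {
  out <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}
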