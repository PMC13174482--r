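# Set bookkeeping that produces the study's headline numbers: shared vs
# condition-specific summit windows, accessibility x cistrome overlap
# summaries, peak-to-gene collapse, and DEG-to-chromatin association
# classes. Overlap here means colocalization of coordinates, not evidence
# of a direct regulatory interaction.

#' Classify summits as shared or condition-specific between two conditions
#'
#' Each summit is extended to a fixed window of `2 * flank` bp; a summit of
#' condition A is shared iff its window overlaps at least one window of
#' condition B (and symmetrically for B). With asymmetric peak sets the two
#' shared counts can differ, so both are reported, each with its percentage
#' of that condition's total.
#'
#' @param summits_a,summits_b data.frames with `chrom` and `summit`.
#' @param flank bp each side of the summit (default 100).
#' @param sizes named chromosome lengths.
#' @param labels length-2 character vector naming the conditions.
#' @return a `condition_overlap` list: `windows_a`/`windows_b` (with logical
#'   column `shared`), and `summary` holding counts (`n`, `shared`,
#'   `specific` per condition), `pct_shared` per condition (two-decimal,
#'   half-up), and the overlapping window pair count `n_pairs`.
#' @export
classify_condition_overlap <- function(summits_a, summits_b, flank = 100,
                                       sizes, labels = c("a", "b")) {
  wa <- summit_windows(summits_a, flank = flank, sizes = sizes)
  wb <- summit_windows(summits_b, flank = flank, sizes = sizes)
  pairs <- overlap_pairs(wa, wb)
  wa$shared <- seq_len(nrow(wa)) %in% pairs$query
  wb$shared <- seq_len(nrow(wb)) %in% pairs$subject
  summary <- list(
    labels = labels,
    n = c(nrow(wa), nrow(wb)),
    shared = c(sum(wa$shared), sum(wb$shared)),
    specific = c(sum(!wa$shared), sum(!wb$shared)),
    pct_shared = c(pct(sum(wa$shared), nrow(wa)),
                   pct(sum(wb$shared), nrow(wb))),
    n_pairs = nrow(pairs)
  )
  structure(list(windows_a = wa, windows_b = wb, summary = summary,
                 flank = flank),
            class = "condition_overlap")
}

#' Summarize overlap between accessibility windows and a cistrome peak set
#'
#' Counts and proportions in both directions plus the total number of
#' overlapping pairs. The overlapping cistrome subset is returned for
#' downstream gene annotation.
#'
#' @param atac_windows interval data.frame (e.g. summit windows).
#' @param cistrome interval data.frame of cistrome (e.g. CUT&RUN) peaks.
#' @return an `integration_summary` list: `n_query`, `n_subject`,
#'   `n_query_overlapping`, `n_subject_overlapping`, `n_pairs`,
#'   `prop_query`, `prop_subject`, `pct_query`, `pct_subject`, and
#'   `subject_overlapping` (the overlapping cistrome rows).
#' @export
summarize_cistrome_overlap <- function(atac_windows, cistrome) {
  .check_intervals(atac_windows, "atac_windows")
  .check_intervals(cistrome, "cistrome")
  pairs <- overlap_pairs(atac_windows, cistrome)
  q_ov <- unique(pairs$query)
  s_ov <- unique(pairs$subject)
  structure(list(
    n_query = nrow(atac_windows),
    n_subject = nrow(cistrome),
    n_query_overlapping = length(q_ov),
    n_subject_overlapping = length(s_ov),
    n_pairs = nrow(pairs),
    prop_query = if (nrow(atac_windows)) length(q_ov) / nrow(atac_windows) else NA_real_,
    prop_subject = if (nrow(cistrome)) length(s_ov) / nrow(cistrome) else NA_real_,
    pct_query = pct(length(q_ov), nrow(atac_windows)),
    pct_subject = pct(length(s_ov), nrow(cistrome)),
    subject_overlapping = cistrome[sort(s_ov), , drop = FALSE]
  ), class = "integration_summary")
}

#' Collapse peak annotations to a unique gene list
#'
#' @param annotations data.frame from [annotate_peaks()] (needs
#'   `gene_symbol`); rows with missing genes are dropped.
#' @return lexicographically sorted character vector of unique gene symbols.
#' @export
peaks_to_unique_genes <- function(annotations) {
  stopifnot(is.data.frame(annotations), "gene_symbol" %in% names(annotations))
  g <- annotations$gene_symbol
  sort(unique(g[!is.na(g)]), method = "radix")
}

#' Classify differentially expressed genes by chromatin association
#'
#' Each DEG is classed by membership in the two conditions' peak-associated
#' gene sets: `shared` (both), `a_specific`, `b_specific`, or `neither`.
#' Comparison is exact, case-sensitive string match unless
#' `case_insensitive = TRUE`.
#'
#' @param degs character vector of DEG symbols (duplicates are removed with
#'   a warning).
#' @param genes_a,genes_b character vectors of genes associated with
#'   accessible chromatin in each condition.
#' @param case_insensitive fold everything to upper case first.
#' @return a `deg_association` list: `table` (data.frame `gene, in_a, in_b,
#'   class`, sorted by gene) and `counts` (named vector over the four
#'   classes plus `total`).
#' @export
classify_deg_association <- function(degs, genes_a, genes_b,
                                     case_insensitive = FALSE) {
  stopifnot(is.character(degs), is.character(genes_a), is.character(genes_b))
  if (case_insensitive) {
    degs <- toupper(degs); genes_a <- toupper(genes_a); genes_b <- toupper(genes_b)
  }
  if (anyDuplicated(degs)) {
    warning("duplicate DEG symbols removed")
    degs <- unique(degs)
  }
  degs <- sort(degs, method = "radix")
  in_a <- degs %in% genes_a
  in_b <- degs %in% genes_b
  class <- ifelse(in_a & in_b, "shared",
                  ifelse(in_a, "a_specific",
                         ifelse(in_b, "b_specific", "neither")))
  counts <- c(shared = sum(in_a & in_b),
              a_specific = sum(in_a & !in_b),
              b_specific = sum(!in_a & in_b),
              neither = sum(!in_a & !in_b),
              total = length(degs))
  structure(list(
    table = data.frame(gene = degs, in_a = in_a, in_b = in_b, class = class,
                       stringsAsFactors = FALSE),
    counts = counts
  ), class = "deg_association")
}

#' @export
print.condition_overlap <- function(x, ...) {
  s <- x$summary
  cat("Summit-window overlap (flank ", x$flank, " bp)\n", sep = "")
  for (i in 1:2) {
    cat(sprintf("  %s: %d summits, %d shared (%.2f%%), %d specific\n",
                s$labels[i], s$n[i], s$shared[i], s$pct_shared[i],
                s$specific[i]))
  }
  cat("  overlapping window pairs:", s$n_pairs, "\n")
  invisible(x)
}

#' @export
print.integration_summary <- function(x, ...) {
  cat("Interval set overlap\n")
  cat(sprintf("  query:   %d, overlapping %d (%.2f%%)\n",
              x$n_query, x$n_query_overlapping, x$pct_query))
  cat(sprintf("  subject: %d, overlapping %d (%.2f%%)\n",
              x$n_subject, x$n_subject_overlapping, x$pct_subject))
  cat("  pairs:", x$n_pairs, "\n")
  invisible(x)
}

#' @export
print.deg_association <- function(x, ...) {
  cat("DEG chromatin association\n")
  print(x$counts)
  invisible(x)
}
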