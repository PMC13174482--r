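# Comparative-Ct quantification for locus validation qPCR.

#' Fold change by the comparative Ct (2^-ddCt) method
#'
#' Per measurement, `dCt = ct_target - ct_reference`. The group-level
#' `ddCt` is `mean(dCt treated) - mean(dCt control)` and the fold change is
#' `2^-ddCt`; the control group is 1 by construction. Per-replicate fold
#' changes (each replicate's dCt against the control mean) are also
#' returned for dispersion display.
#'
#' @param treated,control data.frames with numeric columns `ct_target` and
#'   `ct_reference`, one row per replicate. Ct values outside 5-40 cycles
#'   trigger a warning.
#' @return a `ddct_result` list: `fold_change`, `ddct`, `dct_treated`,
#'   `dct_control`, `per_replicate` (data.frame `condition, replicate, dct,
#'   fold_change`).
#' @export
ddct_fold_change <- function(treated, control) {
  check <- function(d, what) {
    stopifnot(is.data.frame(d))
    if (!all(c("ct_target", "ct_reference") %in% names(d))) {
      stop(what, " needs columns ct_target and ct_reference")
    }
    if (!nrow(d)) stop(what, " group is empty")
    ct <- c(d$ct_target, d$ct_reference)
    if (any(!is.finite(ct))) stop(what, ": non-finite Ct value")
    if (any(ct < 5 | ct > 40)) {
      warning(what, ": Ct value outside the typical 5-40 cycle range")
    }
    d$ct_target - d$ct_reference
  }
  dct_t <- check(treated, "treated")
  dct_c <- check(control, "control")
  ddct <- mean(dct_t) - mean(dct_c)
  per <- data.frame(
    condition = c(rep("treated", length(dct_t)), rep("control", length(dct_c))),
    replicate = c(seq_along(dct_t), seq_along(dct_c)),
    dct = c(dct_t, dct_c),
    fold_change = 2^-(c(dct_t, dct_c) - mean(dct_c)),
    stringsAsFactors = FALSE
  )
  structure(list(fold_change = 2^-ddct, ddct = ddct,
                 dct_treated = dct_t, dct_control = dct_c,
                 per_replicate = per),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("2^-ddCt fold change: %.4g (ddCt = %.4g; %d treated, %d control replicates)\n",
              x$fold_change, x$ddct,
              length(x$dct_treated), length(x$dct_control)))
  invisible(x)
}
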