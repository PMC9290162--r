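#' Coverage quality control
#'
#' Verifies that every reference position is covered deeply enough that no
#' mutation site could be missed. A sample failing this check must not be
#' reported at all — a negative call at an uncovered site would be unsafe —
#' so the pipeline records the failure and stops.
#'
#' @param pileup A [build_pileup()] result.
#' @param min_coverage Minimum reads per position (default 100).
#' @param region Optional integer vector of positions to evaluate (default:
#'   the whole reference).
#' @return Object of class `qc_result`: `passed`, `min_observed_coverage`,
#'   `failing_positions`, `threshold_used`.
#' @export
check_coverage <- function(pileup, min_coverage = 100L, region = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  min_coverage <- as.integer(min_coverage)
  pos <- if (is.null(region)) seq_len(pileup$ref_length) else as.integer(region)
  cov <- pileup$coverage[pos]
  failing <- pos[cov < min_coverage]
  structure(
    list(passed = length(failing) == 0,
         min_observed_coverage = if (length(cov)) min(cov) else 0L,
         failing_positions = failing,
         threshold_used = min_coverage),
    class = "qc_result")
}

#' Per-position coverage profile
#'
#' @param pileup A [build_pileup()] result.
#' @return List: `coverage` (integer vector over reference positions),
#'   `min`, `median`, `max`.
#' @export
coverage_profile <- function(pileup) {
  stopifnot(inherits(pileup, "pileup"))
  cov <- pileup$coverage
  list(coverage = cov,
       min = if (length(cov)) min(cov) else 0L,
       median = if (length(cov)) median(cov) else 0L,
       max = if (length(cov)) max(cov) else 0L)
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("Coverage QC: %s (min observed %d, threshold %d%s)\n",
              if (x$passed) "PASSED" else "FAILED",
              x$min_observed_coverage, x$threshold_used,
              if (x$passed) ""
              else sprintf(", %d failing positions",
                           length(x$failing_positions))))
  invisible(x)
}
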