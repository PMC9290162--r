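#' Run the full analysis pipeline on one sample
#'
#' Executes the whole workflow on a FASTQ of high-accuracy amplicon reads:
#' (1) primer filtering and orientation, (2) dominant-isoform assignment,
#' (3) coverage quality control (the analysis stops here, with status
#' `qc_failed`, when any position is under-covered), (4) de novo
#' substitution scan, (5) catalogued-mutation calling with VAFs,
#' (6) clonal phasing when at least two positive mutations co-occur,
#' (7) optional persistence to the results store.
#'
#' @param fastq Path to a FASTQ file, or a reads data frame as returned by
#'   [read_fastq()].
#' @param panel An [amplicon_panel()].
#' @param sample_id Sample identifier used in the record and reports.
#' @param seed Seed for the isoform-voting subsample (default 1).
#' @param store Optional results-store path; when given the record is
#'   appended via [store_result()].
#' @param min_span_frac Partial-read threshold, see [align_reads()].
#' @param sample_cap Isoform-voting subsample size, see
#'   [assign_reference()].
#' @param timestamp Run timestamp recorded in the result (defaults to the
#'   current UTC time; fix it for reproducible records).
#' @return A `sample_record`: `sample_id`, `run_timestamp`, `status`
#'   (`"ok"` or `"qc_failed"`), `read_stats`, `isoform_id`,
#'   `isoform_votes`, `qc`, `known_results`, `de_novo`, `clones` (or
#'   `NULL`), `cooccurrence`, `pipeline_version`, `panel_hash`.
#' @export
run_sample <- function(fastq, panel, sample_id, seed = 1L, store = NULL,
                       min_span_frac = 0.5, sample_cap = 500L,
                       timestamp = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"))
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  timestamp <- timestamp %||%
    format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  version <- as.character(utils::packageVersion("lramp"))

  filtered <- filter_reads(reads, panel)
  base <- list(sample_id = as.character(sample_id),
               run_timestamp = timestamp,
               read_stats = filtered$stats,
               pipeline_version = version,
               panel_name = panel$name, panel_hash = panel$panel_hash,
               seed = as.integer(seed))

  if (nrow(filtered$kept) == 0) {
    rec <- structure(c(base, list(
      status = "qc_failed", isoform_id = NULL, isoform_votes = NULL,
      qc = list(passed = FALSE, min_observed_coverage = 0L,
                failing_positions = integer(), threshold_used =
                  panel$min_coverage),
      known_results = NULL, de_novo = NULL, clones = NULL,
      cooccurrence = NULL)), class = "sample_record")
    if (!is.null(store)) rec$record_id <- store_result(rec, store)
    return(rec)
  }

  assignment <- assign_reference(filtered$kept, panel,
                                 sample_cap = sample_cap, seed = seed)
  ref <- assignment$chosen
  alignments <- align_reads(filtered$kept, ref,
                            min_span_frac = min_span_frac)
  pileup <- build_pileup(alignments)
  qc <- check_coverage(pileup, panel$min_coverage)

  if (!qc$passed) {
    rec <- structure(c(base, list(
      status = "qc_failed", isoform_id = ref$isoform_id,
      isoform_votes = assignment$votes, qc = unclass(qc),
      known_results = NULL, de_novo = NULL, clones = NULL,
      cooccurrence = NULL)), class = "sample_record")
    if (!is.null(store)) rec$record_id <- store_result(rec, store)
    return(rec)
  }

  de_novo <- scan_de_novo(pileup, ref, panel)
  known <- call_known(alignments, ref, panel)

  positive <- known[known$status %in% c("positive", "clinically_reportable"),
                    , drop = FALSE]
  clones <- NULL
  cooc <- NULL
  if (nrow(positive) >= 2) {
    haps <- extract_haplotypes(alignments, ref, positive$label)
    clones <- unclass(clonal_distribution(haps))
    if (clones$phasing_available) {
      pairs <- utils::combn(positive$label, 2)
      cooc <- lapply(seq_len(ncol(pairs)), function(k) {
        ct <- structure(clones, class = "clone_table")
        r <- cooccurrence_test(ct, pairs[1, k], pairs[2, k])
        list(a = pairs[1, k], b = pairs[2, k], descriptor = r$descriptor,
             counts = as.list(r$counts))
      })
    }
  }

  rec <- structure(c(base, list(
    status = "ok", isoform_id = ref$isoform_id,
    isoform_votes = assignment$votes, isoform_tie = assignment$tie,
    qc = unclass(qc),
    coverage = list(min = min(pileup$coverage),
                    median = stats::median(pileup$coverage),
                    max = max(pileup$coverage)),
    n_partial_reads = pileup$n_partial,
    known_results = known, de_novo = de_novo,
    clones = clones, cooccurrence = cooc)), class = "sample_record")
  if (!is.null(store)) rec$record_id <- store_result(rec, store)
  rec
}

#' @export
print.sample_record <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
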