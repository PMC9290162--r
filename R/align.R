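#' Default alignment scoring scheme
#'
#' Match +2, mismatch -4, gap open -6 (charged for the first gapped base),
#' gap extension -1 (each additional base). Shared by read scoring, isoform
#' voting and pileup construction so every stage sees the same alignments.
#'
#' @return Named list of scores.
#' @export
default_scoring <- function() {
  list(match = 2L, mismatch = -4L, gap_open = -6L, gap_extend = -1L)
}

#' Align one read to a reference
#'
#' Semi-global affine-gap alignment: the read is aligned end to end while
#' reference overhangs on either side are free, the right shape for
#' near-full-length amplicon reads. The traceback is deterministic, with
#' ties resolved in favour of match/mismatch over deletion over insertion,
#' and the leftmost end column on equal scores. Exact within an adaptive
#' band sized to the read/reference length difference plus `band_extra`
#' (band_extra <= 0 forces the full dynamic program).
#'
#' @param sequence Read sequence (reference strand, primers trimmed).
#' @param ref An [isoform_reference()] or a plain DNA string.
#' @param scoring Scoring scheme, see [default_scoring()].
#' @param band_extra Band slack in bases (default 32).
#' @return List of class `read_alignment`: `score`, `start`, `end` (1-based
#'   observed reference span), `aligned_pairs` (named character vector,
#'   reference position -> observed base, `-` for deletion), `insertions`
#'   (data frame `after`, `seq`).
#' @export
align_read <- function(sequence, ref, scoring = default_scoring(),
                       band_extra = 32L) {
  ref_seq <- if (inherits(ref, "isoform_reference")) ref$sequence else ref
  res <- .cpp_align_batch(sequence, ref_seq, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          as.integer(band_extra), TRUE)
  obs <- as.integer(res$obs[, 1])
  span <- if (res$start[1] > 0) res$start[1]:res$end[1] else integer()
  ins <- res$insertions[[1]]
  structure(
    list(score = res$score[1], start = res$start[1], end = res$end[1],
         aligned_pairs = setNames(OBS_BASES[obs[span]], span),
         insertions = if (is.null(ins))
           data.frame(after = integer(), seq = character())
         else data.frame(after = ins$after, seq = ins$seq,
                         stringsAsFactors = FALSE)),
    class = "read_alignment")
}

#' Align a set of oriented reads to the assigned reference
#'
#' Batch version of [align_read()] returning a compact per-read observation
#' matrix (one column per read, one row per reference position) from which
#' the pileup, the per-read codon calls and the phasing genotypes are all
#' derived. Reads whose observed reference span covers less than
#' `min_span_frac` of the reference are flagged partial; they are excluded
#' from the pileup and from phasing (chimeric or truncated molecules would
#' otherwise distort VAFs) but counted in the run summary.
#'
#' @param reads Data frame with `read_id`, `sequence` (from
#'   [filter_reads()]).
#' @param ref An [isoform_reference()].
#' @param scoring Scoring scheme.
#' @param min_span_frac Minimum observed fraction of the reference (default
#'   0.5).
#' @param band_extra Band slack, see [align_read()].
#' @return Object of class `read_alignments`: `read_id`, `score`, `start`,
#'   `end`, `partial` (logical), `obs` (raw matrix, codes 0-6), `insertions`
#'   (list), `ref_length`.
#' @export
align_reads <- function(reads, ref, scoring = default_scoring(),
                        min_span_frac = 0.5, band_extra = 32L) {
  stopifnot(inherits(ref, "isoform_reference"))
  m <- nchar(ref$sequence)
  res <- .cpp_align_batch(reads$sequence, ref$sequence,
                          scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          as.integer(band_extra), TRUE)
  span <- ifelse(res$start > 0, res$end - res$start + 1L, 0L)
  structure(
    list(read_id = reads$read_id, score = res$score,
         start = res$start, end = res$end,
         partial = span < min_span_frac * m,
         obs = res$obs, insertions = res$insertions,
         ref_length = m, isoform_id = ref$isoform_id),
    class = "read_alignments")
}

#' Build a per-position base-count pileup
#'
#' Accumulates, at every reference position, the number of reads observing
#' A, C, G, T, N or a deletion there. Deletions count toward coverage (a
#' read spanning a deletion did observe the locus); N does not; insertions
#' are tabulated in a side table and never enter substitution counts.
#' Partial reads are excluded.
#'
#' @param alignments A `read_alignments` object from [align_reads()].
#' @return Object of class `pileup`: `counts` (6 x ref_length integer
#'   matrix, rows A/C/G/T/N/del), `coverage` (integer vector), `insertions`
#'   (data frame `after`, `seq`, `n`), `n_reads`, `n_partial`, `ref_length`.
#' @export
build_pileup <- function(alignments) {
  stopifnot(inherits(alignments, "read_alignments"))
  keep <- !alignments$partial
  counts <- .cpp_pileup(alignments$obs, keep)
  rownames(counts) <- OBS_BASES
  coverage <- as.integer(colSums(counts[c("A", "C", "G", "T", "-"), ,
                                        drop = FALSE]))
  ins <- alignments$insertions[keep]
  ins <- ins[!vapply(ins, is.null, TRUE)]
  ins_tab <- if (length(ins)) {
    after <- unlist(lapply(ins, `[[`, "after"), use.names = FALSE)
    seqv <- unlist(lapply(ins, `[[`, "seq"), use.names = FALSE)
    tab <- table(paste(after, seqv))
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    out <- data.frame(after = as.integer(vapply(parts, `[[`, "", 1)),
                      seq = vapply(parts, `[[`, "", 2),
                      n = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(out$after, out$seq), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else data.frame(after = integer(), seq = character(), n = integer())
  structure(
    list(counts = counts, coverage = coverage, insertions = ins_tab,
         n_reads = sum(keep), n_partial = sum(!keep),
         ref_length = alignments$ref_length,
         isoform_id = alignments$isoform_id),
    class = "pileup")
}

#' Export a pileup as a per-position table
#'
#' @param pileup A [build_pileup()] result.
#' @param ref Optional [isoform_reference()] supplying the reference base
#'   column.
#' @param path Optional TSV output path.
#' @return Data frame: `position`, `ref` (if supplied), `A`, `C`, `G`, `T`,
#'   `N`, `del`, `coverage`.
#' @export
pileup_table <- function(pileup, ref = NULL, path = NULL) {
  tab <- data.frame(position = seq_len(pileup$ref_length))
  if (!is.null(ref))
    tab$ref <- strsplit(ref$sequence, "")[[1]]
  tab <- cbind(tab, t(pileup$counts))
  names(tab)[names(tab) == "-"] <- "del"
  tab$coverage <- pileup$coverage
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
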