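#' Alignment score of a read against a candidate isoform
#'
#' Semi-global score under the shared scoring scheme; higher is better.
#' Used for isoform voting.
#'
#' @param sequence Read sequence (oriented, primer-trimmed).
#' @param ref An [isoform_reference()].
#' @param scoring Scoring scheme.
#' @return Integer score (vectorized over `sequence`).
#' @export
score_read <- function(sequence, ref, scoring = default_scoring()) {
  stopifnot(inherits(ref, "isoform_reference"))
  .cpp_align_batch(sequence, ref$sequence, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend, 64L, FALSE)$score
}

#' Determine the dominant isoform and assign it as the sample reference
#'
#' Exon usage of the fusion transcript can vary between samples, so the
#' reference is chosen per sample: a subsample of reads (a seeded random
#' subset of at most `sample_cap`) each votes for its best-scoring candidate
#' isoform, and the isoform with the most votes becomes the reference for
#' all subsequent steps. Ties break deterministically by panel order and are
#' flagged. Reads voting for minority isoforms are NOT discarded; they
#' simply align to the chosen reference with gaps.
#'
#' @param reads Data frame of oriented reads (from [filter_reads()]).
#' @param panel An [amplicon_panel()].
#' @param sample_cap Maximum reads scored (default 500).
#' @param seed Seed for the subsampling shuffle (default 1).
#' @return List: `chosen` (an [isoform_reference()]), `votes` (data frame
#'   `isoform_id`, `votes`, `mean_score`), `tie` (logical),
#'   `n_scored`.
#' @export
assign_reference <- function(reads, panel, sample_cap = 500L, seed = 1L) {
  stopifnot(inherits(panel, "amplicon_panel"))
  if (nrow(reads) == 0)
    stop("cannot assign a reference isoform: no reads", call. = FALSE)
  isoforms <- panel$isoforms
  if (length(isoforms) == 1) {
    return(list(chosen = isoforms[[1]],
                votes = data.frame(isoform_id = names(isoforms),
                                   votes = nrow(reads),
                                   mean_score = NA_real_),
                tie = FALSE, n_scored = 0L))
  }
  idx <- .with_seed(seed, sample.int(nrow(reads)))
  idx <- idx[seq_len(min(nrow(reads), sample_cap))]
  seqs <- reads$sequence[idx]
  scores <- vapply(isoforms, function(iso) score_read(seqs, iso),
                   numeric(length(seqs)))
  if (length(seqs) == 1) scores <- matrix(scores, nrow = 1)
  best <- max.col(scores, ties.method = "first")  # panel order on ties
  votes <- tabulate(best, nbins = length(isoforms))
  mean_score <- vapply(seq_along(isoforms), function(k) {
    if (votes[k] == 0) NA_real_ else mean(scores[best == k, k])
  }, 0)
  top <- which(votes == max(votes))
  list(chosen = isoforms[[top[1]]],
       votes = data.frame(isoform_id = names(isoforms), votes = votes,
                          mean_score = mean_score,
                          stringsAsFactors = FALSE),
       tie = length(top) > 1, n_scored = length(seqs))
}
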