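#' Read a FASTQ file of amplicon reads
#'
#' Plain or gzipped FASTQ. Qualities are carried along for auditing but the
#' pipeline does not weight by them (circular-consensus reads are already
#' consensus-called).
#'
#' @param path FASTQ path.
#' @return Data frame with columns `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  if (file.size(path) == 0 ||
      (grepl("\\.gz$", path) && length(readLines(path, n = 1)) == 0)) {
    return(data.frame(read_id = character(), sequence = character(),
                      qualities = character(), stringsAsFactors = FALSE))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    read_id = sub("\\s.*$", "", unname(names(x))),
    sequence = unname(as.character(x)),
    qualities = unname(as.character(S4Vectors::mcols(x)$qualities)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads Data frame with `read_id`, `sequence` and optionally
#'   `qualities` (constant Q40 written when absent).
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qualities
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Anchored primer comparison
#'
#' Compares a primer against an equal-length window by Hamming distance.
#' `N` (in either sequence) counts as a mismatch. A window shorter than the
#' primer never matches.
#'
#' @param window Character vector of windows.
#' @param primer Single primer sequence.
#' @param max_mismatches Mismatches tolerated.
#' @return Data frame with logical `matched` and integer `mismatches`.
#' @export
match_primer <- function(window, primer, max_mismatches) {
  mm <- .hamming_to(window, primer)
  data.frame(matched = !is.na(mm) & mm <= max_mismatches,
             mismatches = mm)
}

# vectorized Hamming distance of each string against one probe; NA when the
# string is shorter than the probe
.hamming_to <- function(x, probe) {
  k <- nchar(probe)
  out <- rep(NA_integer_, length(x))
  long <- !is.na(x) & nchar(x) >= k
  if (!any(long)) return(out)
  mm <- integer(sum(long))
  xs <- x[long]
  pc <- strsplit(probe, "")[[1]]
  for (p in seq_len(k)) {
    ch <- substr(xs, p, p)
    mm <- mm + (ch != pc[p] | ch == "N" | pc[p] == "N")
  }
  out[long] <- mm
  out
}

#' Orient a read to the reference strand and trim its primers
#'
#' Tests the forward layout (forward primer at the 5' end, reverse complement
#' of the reverse primer at the 3' end) and the reverse layout (the same
#' after reverse-complementing the read). On success the read is returned on
#' the reference strand with both primer spans removed.
#'
#' @param read One-row data frame (or list) with `read_id` and `sequence`.
#' @param panel An [amplicon_panel()].
#' @return A list with `read_id`, `sequence`, `original_orientation`
#'   (`"forward"` or `"reverse"`), or a rejection with class
#'   `read_rejection` and a `reason` field in
#'   `c("no_5prime_primer", "no_3prime_primer", "both_orientations_fail")`.
#' @export
orient_and_trim <- function(read, panel) {
  res <- .orient_batch(read$sequence, panel)
  if (is.na(res$orientation[1]))
    return(structure(list(read_id = read$read_id, reason = res$reason[1]),
                     class = "read_rejection"))
  list(read_id = read$read_id, sequence = res$sequence[1],
       original_orientation = res$orientation[1])
}

# vectorized orientation test; returns data.frame(sequence, orientation, reason)
.orient_batch <- function(seqs, panel) {
  lf <- nchar(panel$forward_primer)
  lr <- nchar(panel$reverse_primer)
  mm <- panel$max_primer_mismatches
  len <- nchar(seqs)
  rc_rev <- .revcomp(panel$reverse_primer)
  rc_fwd <- .revcomp(panel$forward_primer)

  head_f <- substr(seqs, 1, lf)
  tail_f <- substr(seqs, len - lr + 1, len)
  head_r <- substr(seqs, 1, lr)
  tail_r <- substr(seqs, len - lf + 1, len)

  f5 <- .hamming_to(head_f, panel$forward_primer) <= mm
  f3 <- .hamming_to(tail_f, rc_rev) <= mm
  r5 <- .hamming_to(head_r, panel$reverse_primer) <= mm
  r3 <- .hamming_to(tail_r, rc_fwd) <= mm
  f5[is.na(f5)] <- FALSE; f3[is.na(f3)] <- FALSE
  r5[is.na(r5)] <- FALSE; r3[is.na(r3)] <- FALSE
  long_enough <- len > lf + lr

  fwd_ok <- f5 & f3 & long_enough
  rev_ok <- r5 & r3 & long_enough & !fwd_ok

  sequence <- rep(NA_character_, length(seqs))
  orientation <- rep(NA_character_, length(seqs))
  reason <- rep(NA_character_, length(seqs))

  if (any(fwd_ok))
    sequence[fwd_ok] <- substr(seqs[fwd_ok], lf + 1, len[fwd_ok] - lr)
  orientation[fwd_ok] <- "forward"
  if (any(rev_ok))
    sequence[rev_ok] <- .revcomp(substr(seqs[rev_ok], lr + 1,
                                        len[rev_ok] - lf))
  orientation[rev_ok] <- "reverse"

  fail <- !fwd_ok & !rev_ok
  # reason bookkeeping: a 5' hit in either layout narrows the failure to the
  # matching 3' end; otherwise the 5' end itself was never found
  reason[fail & !f5 & !r5] <- "no_5prime_primer"
  reason[fail & (f5 | r5)] <- "no_3prime_primer"
  reason[fail & !long_enough] <- "both_orientations_fail"
  reason[fail & is.na(reason)] <- "both_orientations_fail"
  data.frame(sequence = sequence, orientation = orientation, reason = reason,
             stringsAsFactors = FALSE)
}

#' Filter a read set down to primer-confirmed, oriented amplicon reads
#'
#' Keeps only reads carrying both expected primer sequences (within the
#' panel's mismatch tolerance) at their ends, in either orientation, so that
#' only on-target amplicon molecules enter the analysis. Kept reads are
#' returned on the reference strand with the primer spans trimmed off.
#'
#' @param reads Data frame from [read_fastq()] (columns `read_id`,
#'   `sequence`).
#' @param panel An [amplicon_panel()].
#' @return List with `kept` (data frame: `read_id`, `sequence`,
#'   `original_orientation`, input order preserved) and `stats` (list:
#'   `total`, `kept`, `rejected` named by reason).
#' @export
filter_reads <- function(reads, panel) {
  reasons <- c("no_5prime_primer", "no_3prime_primer",
               "both_orientations_fail")
  if (nrow(reads) == 0) {
    return(list(
      kept = data.frame(read_id = character(), sequence = character(),
                        original_orientation = character(),
                        stringsAsFactors = FALSE),
      stats = list(total = 0L, kept = 0L,
                   rejected = setNames(rep(0L, 3), reasons))))
  }
  res <- .orient_batch(reads$sequence, panel)
  ok <- !is.na(res$orientation)
  kept <- data.frame(read_id = reads$read_id[ok],
                     sequence = res$sequence[ok],
                     original_orientation = res$orientation[ok],
                     stringsAsFactors = FALSE)
  rej <- table(factor(res$reason[!ok], levels = reasons))
  list(kept = kept,
       stats = list(total = nrow(reads), kept = nrow(kept),
                    rejected = setNames(as.integer(rej), reasons)))
}
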