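#' Load per-sample call sets from a TSV file
#'
#' Expected columns: `sample`, `method`, `label`, `vaf_percent`. A row with
#' label `-` marks a sample/method pair with no calls (so that fully
#' negative samples still appear). VAF-free methods (Sanger-like) carry
#' `NA` in `vaf_percent`.
#'
#' @param path TSV path.
#' @return Data frame with those four columns (no-call rows retained).
#' @export
load_callsets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character"))
  need <- c("sample", "method", "label", "vaf_percent")
  if (!all(need %in% names(df)))
    stop("call-set file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$vaf_percent <- suppressWarnings(as.numeric(df$vaf_percent))
  df
}

#' The packaged two-method validation call sets
#'
#' A transcription of the 39-sample parallel validation: for each sample,
#' the mutations reported by conventional Sanger sequencing (no VAF) and by
#' the long-read assay (VAF percentages). One long-read call is recorded
#' with the codon-only label `E255` because the original report did not
#' state the alternate amino acid; it is matched by codon prefix, not
#' guessed.
#'
#' @return Data frame as from [load_callsets()].
#' @export
table1_callsets <- function() {
  load_callsets(system.file("extdata", "table1_callsets.tsv",
                            package = "lramp"))
}

# label helpers: "E255K" -> prefix "E255"; a codon-only label like "E255"
# is ambiguous (no alternate amino acid stated)
.label_prefix <- function(label) sub("^([A-Z][0-9]+).*$", "\\1", label)
.label_ambiguous <- function(label) grepl("^[A-Z][0-9]+$", label)

#' Concordance between a reference method and a VAF-bearing method
#'
#' Compares per-sample mutation calls from a reference method `a`
#' (Sanger-like, no VAFs) against method `b` (VAF-bearing). Labels match by
#' exact string; an ambiguous codon-only label (e.g. `E255`) on either side
#' matches any label sharing its codon. `only_in_b_above_clinical`
#' additionally requires the b-side VAF to exceed the clinical cutoff.
#'
#' @param a,b Data frames with columns `sample`, `label`, `vaf_percent`
#'   (`-` rows mark samples without calls). Both must cover the same set of
#'   samples.
#' @param clinical_cutoff Fraction (default 0.01).
#' @return Object of class `concordance_summary`: `n_samples`,
#'   `per_sample` (data frame `sample`, `class` in `both_negative` /
#'   `full_agreement` / `b_superset` / `other`), and `totals` (list:
#'   `mutations_in_a`, `mutations_in_a_missed_by_b`, `mutations_only_in_b`,
#'   `only_in_b_above_clinical`, `samples_both_negative`,
#'   `samples_with_mutations`, `samples_full_agreement`,
#'   `samples_b_found_more`).
#' @export
compare_call_sets <- function(a, b, clinical_cutoff = 0.01) {
  sa <- unique(as.character(a$sample))
  sb <- unique(as.character(b$sample))
  if (!setequal(sa, sb))
    stop("call sets cover different samples: ",
         paste(union(setdiff(sa, sb), setdiff(sb, sa)), collapse = ", "),
         call. = FALSE)
  samples <- sa[order(suppressWarnings(as.numeric(sa)), sa)]

  matched_in <- function(label, other_labels) {
    if (label %in% other_labels) return(TRUE)
    if (.label_ambiguous(label))
      return(.label_prefix(label) %in% .label_prefix(other_labels))
    .label_prefix(label) %in%
      other_labels[.label_ambiguous(other_labels)]
  }

  per_sample <- data.frame(sample = samples, class = NA_character_,
                           stringsAsFactors = FALSE)
  tot <- list(mutations_in_a = 0L, mutations_in_a_missed_by_b = 0L,
              mutations_only_in_b = 0L, only_in_b_above_clinical = 0L,
              samples_both_negative = 0L, samples_with_mutations = 0L,
              samples_full_agreement = 0L, samples_b_found_more = 0L)

  for (k in seq_along(samples)) {
    s <- samples[k]
    arows <- a[as.character(a$sample) == s & a$label != "-", , drop = FALSE]
    brows <- b[as.character(b$sample) == s & b$label != "-", , drop = FALSE]
    A <- arows$label; B <- brows$label
    tot$mutations_in_a <- tot$mutations_in_a + length(A)
    a_missed <- vapply(A, function(l) !matched_in(l, B), TRUE)
    b_only <- vapply(B, function(l) !matched_in(l, A), TRUE)
    tot$mutations_in_a_missed_by_b <-
      tot$mutations_in_a_missed_by_b + sum(a_missed)
    tot$mutations_only_in_b <- tot$mutations_only_in_b + sum(b_only)
    if (any(b_only))
      tot$only_in_b_above_clinical <- tot$only_in_b_above_clinical +
        sum(b_only & !is.na(brows$vaf_percent) &
              brows$vaf_percent > 100 * clinical_cutoff)
    cls <-
      if (length(A) == 0 && length(B) == 0) "both_negative"
      else if (!any(a_missed) && !any(b_only)) "full_agreement"
      else if (!any(a_missed) && any(b_only)) "b_superset"
      else "other"
    per_sample$class[k] <- cls
    switch(cls,
           both_negative = tot$samples_both_negative <-
             tot$samples_both_negative + 1L,
           full_agreement = tot$samples_full_agreement <-
             tot$samples_full_agreement + 1L,
           b_superset = tot$samples_b_found_more <-
             tot$samples_b_found_more + 1L,
           NULL)
  }
  tot$samples_with_mutations <- length(samples) - tot$samples_both_negative
  structure(list(n_samples = length(samples), per_sample = per_sample,
                 totals = tot),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Concordance over %d samples\n", x$n_samples))
  cat(sprintf("  reference-method mutations: %d (missed by comparator: %d)\n",
              t$mutations_in_a, t$mutations_in_a_missed_by_b))
  cat(sprintf("  comparator-only mutations:  %d (%d above the clinical cutoff)\n",
              t$mutations_only_in_b, t$only_in_b_above_clinical))
  cat(sprintf("  samples: %d double-negative, %d with mutations (%d full agreement, %d comparator found more)\n",
              t$samples_both_negative, t$samples_with_mutations,
              t$samples_full_agreement, t$samples_b_found_more))
  invisible(x)
}
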