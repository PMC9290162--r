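#' Classify a variant allele frequency against the panel thresholds
#'
#' Boundary semantics follow the clinical policy: a VAF at or above the
#' positive cutoff (default 0.5\%, detection was validated down to that
#' level, hence inclusive) is `positive`; only VAFs strictly above the
#' clinical cutoff (default 1\%) are `clinically_reportable`.
#'
#' @param vaf Numeric vector of fractions in `[0, 1]` (NA allowed).
#' @param panel An [amplicon_panel()] supplying the cutoffs.
#' @return Character vector:
#'   `negative` | `positive` | `clinically_reportable`.
#' @export
classify <- function(vaf, panel) {
  stopifnot(all(is.na(vaf) | (vaf >= 0 & vaf <= 1)))
  ifelse(is.na(vaf), NA_character_,
         ifelse(vaf < panel$positive_cutoff, "negative",
                ifelse(vaf <= panel$clinical_cutoff, "positive",
                       "clinically_reportable")))
}

# per-read translated amino acid at one codon of the reference frame;
# NA where the read's codon is interrupted by a deletion, an N, or is not
# fully covered, or for partial reads
.codon_translations <- function(alignments, ref, codon_number) {
  cp <- codon_to_positions(ref, codon_number)
  o <- alignments$obs[cp, , drop = FALSE]
  b1 <- as.integer(o[1, ]); b2 <- as.integer(o[2, ]); b3 <- as.integer(o[3, ])
  good <- b1 >= 1 & b1 <= 4 & b2 >= 1 & b2 <= 4 & b3 >= 1 & b3 <= 4 &
    !alignments$partial
  aa <- rep(NA_character_, length(b1))
  if (any(good)) {
    codon <- paste0(OBS_BASES[b1[good]], OBS_BASES[b2[good]],
                    OBS_BASES[b3[good]])
    aa[good] <- translate_codon(codon)
  }
  aa
}

#' Call all catalogued mutations with per-read codon-level VAFs
#'
#' Every panel mutation is assessed in every sample, negatives included
#' (the report must assert absence explicitly). Counting is per READ at the
#' codon level — a read supports a mutation when its translated codon equals
#' the alternate amino acid — so that distinct substitutions at one codon
#' (F359I vs F359V vs F359C) are resolved separately, which per-nucleotide
#' counting cannot do.
#'
#' The VAF denominator is the number of reads whose codon translates to the
#' reference amino acid or to a catalogued alternate at that codon.
#' Codons interrupted by a deletion or N are excluded (`codon_coverage`
#' counts the unambiguous codons), and codons whose translation matches no
#' catalogued allele — overwhelmingly sequencing-error artifacts — are
#' reported under `other_reads` but carry no allele information, so they do
#' not dilute the VAF. This keeps the estimator unbiased across the whole
#' VAF range.
#'
#' @param alignments A `read_alignments` object ([align_reads()]).
#' @param ref The assigned [isoform_reference()].
#' @param panel An [amplicon_panel()].
#' @return Data frame, one row per panel mutation: `label`, `ref_aa`,
#'   `codon`, `alt_aa`, `supporting_reads`, `ref_reads`, `other_reads`,
#'   `codon_coverage`, `vaf`, `status`.
#' @export
call_known <- function(alignments, ref, panel) {
  stopifnot(inherits(alignments, "read_alignments"),
            inherits(panel, "amplicon_panel"))
  muts <- panel$known_mutations
  if (length(muts) == 0)
    return(data.frame(label = character(), ref_aa = character(),
                      codon = integer(), alt_aa = character(),
                      supporting_reads = integer(), ref_reads = integer(),
                      other_reads = integer(), codon_coverage = integer(),
                      vaf = numeric(), status = character()))
  codons <- unique(vapply(muts, `[[`, 0L, "codon_number"))
  aa_by_codon <- lapply(setNames(codons, codons), function(cn)
    tryCatch(.codon_translations(alignments, ref, cn),
             error = function(e) NULL))
  alts_at <- lapply(setNames(codons, codons), function(cn)
    vapply(Filter(function(m) m$codon_number == cn, muts), `[[`, "",
           "alt_aa"))
  rows <- lapply(muts, function(m) {
    aa <- aa_by_codon[[as.character(m$codon_number)]]
    if (is.null(aa))
      return(data.frame(label = m$label, ref_aa = m$ref_aa,
                        codon = m$codon_number, alt_aa = m$alt_aa,
                        supporting_reads = NA_integer_,
                        ref_reads = NA_integer_, other_reads = NA_integer_,
                        codon_coverage = 0L, vaf = NA_real_,
                        status = "not_assessable"))
    alleles <- c(m$ref_aa, alts_at[[as.character(m$codon_number)]])
    informative <- !is.na(aa)
    supporting <- sum(aa[informative] == m$alt_aa)
    ref_reads <- sum(aa[informative] == m$ref_aa)
    other <- sum(!(aa[informative] %in% alleles))
    denom <- sum(informative) - other
    vaf <- if (denom > 0) supporting / denom else NA_real_
    data.frame(label = m$label, ref_aa = m$ref_aa, codon = m$codon_number,
               alt_aa = m$alt_aa, supporting_reads = supporting,
               ref_reads = ref_reads, other_reads = other,
               codon_coverage = sum(informative), vaf = vaf,
               status = if (is.na(vaf)) "not_assessable"
               else if (supporting < panel$min_alt_reads) "negative"
               else classify(vaf, panel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' De novo scan for nucleotide substitutions
#'
#' Screens every reference position for previously unreported substitutions:
#' any alternate base seen in at least `min_alt_reads` reads and at a
#' nucleotide-level VAF at or above the positive cutoff is reported. When
#' the position is coding, an amino-acid change label is derived by
#' substituting the alternate base into the reference codon (synonymous
#' changes carry no label).
#'
#' @param pileup A [build_pileup()] result.
#' @param ref The assigned [isoform_reference()].
#' @param panel An [amplicon_panel()].
#' @return Data frame, one row per (position, alt base) call: `position`,
#'   `ref_base`, `alt_base`, `alt_count`, `coverage`, `vaf`, `aa_label`,
#'   `known`, `status`.
#' @export
scan_de_novo <- function(pileup, ref, panel) {
  stopifnot(inherits(pileup, "pileup"), inherits(ref, "isoform_reference"))
  refv <- strsplit(ref$sequence, "")[[1]]
  known_labels <- vapply(panel$known_mutations, `[[`, "", "label")
  calls <- list()
  for (alt in c("A", "C", "G", "T")) {
    cnt <- pileup$counts[alt, ]
    cov <- pileup$coverage
    vaf <- ifelse(cov > 0, cnt / cov, 0)
    hit <- which(refv != alt & cnt >= panel$min_alt_reads &
                   vaf >= panel$positive_cutoff)
    for (p in hit) {
      aa_label <- NA_character_
      ci <- (p - ref$cds_start) %/% 3          # codon index from frame start
      if (p >= ref$cds_start) {
        cstart <- ref$cds_start + 3L * ci
        if (cstart + 2L <= nchar(ref$sequence)) {
          ref_codon <- refv[cstart + 0:2]
          alt_codon <- ref_codon
          alt_codon[p - cstart + 1L] <- alt
          ref_aa <- translate_codon(paste(ref_codon, collapse = ""))
          alt_aa <- translate_codon(paste(alt_codon, collapse = ""))
          if (ref_aa != alt_aa)
            aa_label <- paste0(ref_aa, ref$codon_offset + ci, alt_aa)
        }
      }
      calls[[length(calls) + 1L]] <- data.frame(
        position = p, ref_base = refv[p], alt_base = alt,
        alt_count = cnt[p], coverage = cov[p], vaf = vaf[p],
        aa_label = aa_label,
        known = !is.na(aa_label) && aa_label %in% known_labels,
        status = classify(vaf[p], panel),
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0)
    return(data.frame(position = integer(), ref_base = character(),
                      alt_base = character(), alt_count = integer(),
                      coverage = integer(), vaf = numeric(),
                      aa_label = character(), known = logical(),
                      status = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$position, out$alt_base), , drop = FALSE]
  rownames(out) <- NULL
  out
}
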