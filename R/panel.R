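#' Isoform reference sequence with codon-numbering metadata
#'
#' An isoform reference ties an amplicon DNA sequence to the protein
#' numbering frame used for mutation nomenclature (ABL1 numbering for
#' BCR-ABL1 work): `cds_start` is the 1-based position of the first base of
#' the first complete codon, and `codon_offset` is the amino-acid number
#' assigned to that codon. All downstream codon arithmetic derives from these
#' two fields, so the pipeline never hard-codes gene structure.
#'
#' @param isoform_id Short identifier, e.g. `"e14a2"`.
#' @param sequence Uppercase DNA string (A/C/G/T only), length >= 3.
#' @param cds_start 1-based position of the first base of the first complete
#'   codon in the numbering frame.
#' @param codon_offset Integer amino-acid number assigned to that first codon.
#' @param description Free-text description.
#' @return An object of class `isoform_reference`.
#' @export
isoform_reference <- function(isoform_id, sequence, cds_start, codon_offset,
                              description = "") {
  sequence <- toupper(sequence)
  if (!is.character(isoform_id) || nchar(isoform_id) == 0)
    stop("isoform_id must be a non-empty string", call. = FALSE)
  if (nchar(sequence) < 3 || !.is_dna(sequence))
    stop("isoform '", isoform_id,
         "': sequence must contain only A/C/G/T and be at least 3 bases",
         call. = FALSE)
  cds_start <- as.integer(cds_start)
  codon_offset <- as.integer(codon_offset)
  if (is.na(cds_start) || cds_start < 1 || cds_start > nchar(sequence) - 2)
    stop("isoform '", isoform_id, "': cds_start out of range", call. = FALSE)
  structure(
    list(isoform_id = isoform_id, sequence = sequence,
         cds_start = cds_start, codon_offset = codon_offset,
         description = description),
    class = "isoform_reference")
}

#' Parse a known-mutation label
#'
#' Labels follow the amino-acid change convention `T315I`: reference amino
#' acid, codon number in the protein numbering frame, alternate amino acid.
#'
#' @param label Character label such as `"T315I"`.
#' @return An object of class `known_mutation` with fields `label`, `ref_aa`,
#'   `codon_number`, `alt_aa`.
#' @export
known_mutation <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)([A-Z*])$", label))[[1]]
  if (length(m) != 4)
    stop("malformed mutation label: '", label, "'", call. = FALSE)
  if (m[2] == m[4])
    stop("mutation label '", label,
         "': reference and alternate amino acids must differ", call. = FALSE)
  structure(
    list(label = label, ref_aa = m[2],
         codon_number = as.integer(m[3]), alt_aa = m[4]),
    class = "known_mutation")
}

#' Assemble and validate an amplicon panel
#'
#' The panel bundles everything sample-independent: the PCR primers used to
#' recognize on-target reads, the candidate isoform references, the catalogue
#' of known resistance mutations, and the reporting thresholds. The default
#' thresholds implement the clinical policy for this assay: variants at or
#' above 0.5\% VAF are positive, only variants above 1\% are clinically
#' reportable, and every position must be covered by at least 100 reads.
#'
#' @param forward_primer,reverse_primer Primer sequences as synthesized
#'   (each 5'->3' on its own strand), length >= 10.
#' @param isoforms List of [isoform_reference()] objects (at least one).
#' @param known_mutations Character vector of mutation labels, or a list of
#'   [known_mutation()] objects. May be empty.
#' @param max_primer_mismatches Mismatches tolerated in each anchored primer
#'   comparison (default 2).
#' @param positive_cutoff Minimum VAF for a positive call (default 0.005).
#' @param clinical_cutoff VAF above which a call is clinically reportable
#'   (default 0.01). Must be >= `positive_cutoff`.
#' @param min_coverage Minimum per-position read coverage required to pass
#'   quality control (default 100).
#' @param min_alt_reads Absolute minimum number of variant-supporting reads
#'   (default 3).
#' @param name Panel name used in reports.
#' @return An object of class `amplicon_panel`.
#' @export
amplicon_panel <- function(forward_primer, reverse_primer, isoforms,
                           known_mutations = character(),
                           max_primer_mismatches = 2,
                           positive_cutoff = 0.005, clinical_cutoff = 0.01,
                           min_coverage = 100, min_alt_reads = 3,
                           name = "unnamed-panel") {
  forward_primer <- toupper(forward_primer)
  reverse_primer <- toupper(reverse_primer)
  for (fld in c("forward_primer", "reverse_primer")) {
    p <- get(fld)
    if (!.is_dna(p) || nchar(p) < 10)
      stop(fld, " must be a DNA string of at least 10 bases", call. = FALSE)
  }
  if (inherits(isoforms, "isoform_reference")) isoforms <- list(isoforms)
  if (length(isoforms) < 1)
    stop("isoforms: at least one isoform reference is required", call. = FALSE)
  ids <- vapply(isoforms, `[[`, "", "isoform_id")
  if (anyDuplicated(ids))
    stop("isoforms: isoform_id values must be unique", call. = FALSE)
  names(isoforms) <- ids

  if (is.character(known_mutations))
    known_mutations <- lapply(known_mutations, known_mutation)
  labels <- vapply(known_mutations, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("known_mutations: labels must be unique", call. = FALSE)

  if (!(positive_cutoff > 0 && positive_cutoff < 1))
    stop("positive_cutoff must lie in (0, 1)", call. = FALSE)
  if (!(clinical_cutoff > 0 && clinical_cutoff < 1))
    stop("clinical_cutoff must lie in (0, 1)", call. = FALSE)
  if (positive_cutoff > clinical_cutoff)
    stop("positive_cutoff must not exceed clinical_cutoff", call. = FALSE)
  if (min_coverage < 1) stop("min_coverage must be >= 1", call. = FALSE)
  if (max_primer_mismatches < 0)
    stop("max_primer_mismatches must be >= 0", call. = FALSE)

  panel <- structure(
    list(name = name,
         forward_primer = forward_primer, reverse_primer = reverse_primer,
         max_primer_mismatches = as.integer(max_primer_mismatches),
         isoforms = isoforms, known_mutations = known_mutations,
         positive_cutoff = positive_cutoff, clinical_cutoff = clinical_cutoff,
         min_coverage = as.integer(min_coverage),
         min_alt_reads = as.integer(min_alt_reads)),
    class = "amplicon_panel")
  .check_panel_consistency(panel)
  panel$panel_hash <- .panel_hash(panel)
  panel
}

# every catalogued mutation must be representable on at least one isoform and,
# on every isoform spanning its codon, the reference codon must translate to
# the stated reference amino acid
.check_panel_consistency <- function(panel) {
  for (mut in panel$known_mutations) {
    seen <- FALSE
    for (iso in panel$isoforms) {
      pos <- tryCatch(codon_to_positions(iso, mut$codon_number),
                      error = function(e) NULL)
      if (is.null(pos)) next
      seen <- TRUE
      codon <- substr(iso$sequence, pos[1], pos[3])
      aa <- translate_codon(codon)
      if (aa != mut$ref_aa)
        stop("panel inconsistency: isoform '", iso$isoform_id,
             "' codon ", mut$codon_number, " (", codon, ") translates to '",
             aa, "' but mutation ", mut$label, " expects '", mut$ref_aa, "'",
             call. = FALSE)
    }
    if (!seen)
      stop("panel inconsistency: no isoform spans codon ", mut$codon_number,
           " required by mutation ", mut$label, call. = FALSE)
  }
  invisible(TRUE)
}

.panel_hash <- function(panel) {
  fields <- panel[c("forward_primer", "reverse_primer", "positive_cutoff",
                    "clinical_cutoff", "min_coverage", "min_alt_reads")]
  fields$isoforms <- lapply(panel$isoforms, unclass)
  fields$mutations <- vapply(panel$known_mutations, `[[`, "", "label")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Load an amplicon panel from a YAML configuration file
#'
#' The configuration is a single YAML (or JSON) document. Isoform sequences
#' are given inline under `sequence` or by a `fasta` path (relative to the
#' configuration file) whose record named after the isoform is used. Omitted
#' thresholds take the panel defaults. See
#' `system.file("extdata", "demo_panel.yaml", package = "lramp")` for a
#' complete example of the schema.
#'
#' @param path Path to the configuration file.
#' @return A validated [amplicon_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path))
    stop("panel config not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("panel config does not parse: ", conditionMessage(e),
                         call. = FALSE))
  for (fld in c("forward_primer", "reverse_primer", "isoforms"))
    if (is.null(cfg[[fld]]))
      stop("panel config: missing required field '", fld, "'", call. = FALSE)
  isoforms <- lapply(cfg$isoforms, function(iso) {
    for (fld in c("isoform_id", "cds_start", "codon_offset"))
      if (is.null(iso[[fld]]))
        stop("panel config: isoform entry missing field '", fld, "'",
             call. = FALSE)
    seq <- iso$sequence
    if (is.null(seq)) {
      if (is.null(iso$fasta))
        stop("panel config: isoform '", iso$isoform_id,
             "' needs either 'sequence' or 'fasta'", call. = FALSE)
      fa_path <- file.path(dirname(path), iso$fasta)
      fa <- Biostrings::readDNAStringSet(fa_path)
      if (!iso$isoform_id %in% names(fa))
        stop("panel config: no FASTA record named '", iso$isoform_id,
             "' in ", fa_path, call. = FALSE)
      seq <- as.character(fa[[iso$isoform_id]])
    }
    isoform_reference(iso$isoform_id, seq, iso$cds_start, iso$codon_offset,
                      description = iso$description %||% "")
  })
  args <- list(
    forward_primer = cfg$forward_primer, reverse_primer = cfg$reverse_primer,
    isoforms = isoforms,
    known_mutations = as.character(unlist(cfg$known_mutations)),
    name = cfg$name %||% tools::file_path_sans_ext(basename(path)))
  for (fld in c("max_primer_mismatches", "positive_cutoff", "clinical_cutoff",
                "min_coverage", "min_alt_reads"))
    if (!is.null(cfg[[fld]])) args[[fld]] <- cfg[[fld]]
  do.call(amplicon_panel, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged demonstration panel
#'
#' Loads the demonstration BCR-ABL1-style panel shipped with the package:
#' two synthetic isoform references (the shorter one lacking a 74-base
#' 5' block, mimicking alternative exon usage), the 15 catalogued kinase
#' domain resistance mutations, and the default clinical thresholds. The
#' isoform sequences are engineered stand-ins on which every catalogued
#' mutation is representable; they are NOT the true BCR-ABL1 transcript.
#' Real deployments supply their own reference FASTA and metadata.
#'
#' @return An [amplicon_panel()].
#' @export
demo_panel <- function() {
  load_panel(system.file("extdata", "demo_panel.yaml", package = "lramp"))
}

#' Reference positions of a protein codon
#'
#' Maps a codon number in the isoform's protein numbering frame to the three
#' consecutive 1-based reference positions holding that codon:
#' `start = cds_start + 3 * (codon_number - codon_offset)`.
#'
#' @param ref An [isoform_reference()].
#' @param codon_number Codon number (>= `codon_offset`).
#' @return Integer vector of length 3.
#' @export
codon_to_positions <- function(ref, codon_number) {
  stopifnot(inherits(ref, "isoform_reference"))
  codon_number <- as.integer(codon_number)
  start <- ref$cds_start + 3L * (codon_number - ref$codon_offset)
  if (codon_number < ref$codon_offset || start + 2L > nchar(ref$sequence))
    stop("codon ", codon_number, " lies outside isoform '", ref$isoform_id,
         "'", call. = FALSE)
  start + 0:2
}

#' Translate a single codon
#'
#' Standard genetic code. Codons containing anything other than A/C/G/T
#' (e.g. N) translate to the undefined marker `"X"`; stops are `"*"`.
#'
#' @param codon Character vector of 3-base DNA strings.
#' @return Character vector of single-letter amino acids.
#' @export
translate_codon <- function(codon) {
  out <- unname(Biostrings::GENETIC_CODE[toupper(codon)])
  out[is.na(out)] <- "X"
  out
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("Amplicon panel '", x$name, "'\n", sep = "")
  cat("  isoforms: ",
      paste(sprintf("%s (%d bp)", names(x$isoforms),
                    vapply(x$isoforms, function(i) nchar(i$sequence), 0L)),
            collapse = ", "), "\n", sep = "")
  cat("  known mutations:", length(x$known_mutations), "\n")
  cat(sprintf("  thresholds: positive >= %.2f%%, clinical > %.2f%%, coverage >= %d, alt reads >= %d\n",
              100 * x$positive_cutoff, 100 * x$clinical_cutoff,
              x$min_coverage, x$min_alt_reads))
  invisible(x)
}
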