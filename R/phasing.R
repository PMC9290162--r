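#' Per-read genotypes over the sample's positive mutation sites
#'
#' Because each read spans the whole amplicon, phasing needs no statistical
#' inference: every read directly reports which of the sample's positive
#' mutations it carries. At each site a read is coded `alt` when its
#' translated codon equals that mutation's alternate amino acid, `ref` when
#' it equals the reference amino acid, and `missing` otherwise (deletion, N,
#' uncovered codon, or an error-corrupted translation).
#'
#' @param alignments A `read_alignments` object ([align_reads()]).
#' @param ref The assigned [isoform_reference()].
#' @param mutations The positive mutations to phase: a character vector of
#'   labels or a list of [known_mutation()] objects (at least 2).
#' @return Character matrix, one row per read (rownames = read ids), one
#'   column per mutation label, entries in `c("ref", "alt", "missing")`.
#' @export
extract_haplotypes <- function(alignments, ref, mutations) {
  if (is.character(mutations)) mutations <- lapply(mutations, known_mutation)
  if (length(mutations) < 2)
    stop("phasing needs at least 2 positive mutations", call. = FALSE)
  geno <- vapply(mutations, function(m) {
    aa <- .codon_translations(alignments, ref, m$codon_number)
    ifelse(is.na(aa), "missing",
           ifelse(aa == m$alt_aa, "alt",
                  ifelse(aa == m$ref_aa, "ref", "missing")))
  }, character(length(alignments$read_id)))
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = 1)
  rownames(geno) <- alignments$read_id
  colnames(geno) <- vapply(mutations, `[[`, "", "label")
  geno[!alignments$partial, , drop = FALSE]
}

#' Aggregate read haplotypes into a clone table
#'
#' Reads with any `missing` site are set aside as non-informative (this
#' keeps the clone-fraction/VAF identity exact); the remaining reads are
#' grouped by their exact mutation set. Clones are listed by descending
#' read count; the wild-type clone (empty mutation set) is always listed.
#'
#' @param haplotypes Matrix from [extract_haplotypes()].
#' @return Object of class `clone_table`: `clones` (data frame `mutations`
#'   — `+`-joined labels, `""` for wild type — `reads`, `fraction`),
#'   `sites`, `n_informative`, `n_noninformative`. When no read is
#'   informative, `phasing_available` is `FALSE` and `clones` is empty.
#' @export
clonal_distribution <- function(haplotypes) {
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) >= 1)
  sites <- colnames(haplotypes)
  informative <- rowSums(haplotypes == "missing") == 0
  n_inf <- sum(informative)
  if (n_inf == 0) {
    return(structure(
      list(clones = data.frame(mutations = character(), reads = integer(),
                               fraction = numeric()),
           sites = sites, n_informative = 0L,
           n_noninformative = nrow(haplotypes) - 0L,
           phasing_available = FALSE),
      class = "clone_table"))
  }
  h <- haplotypes[informative, , drop = FALSE]
  key <- apply(h == "alt", 1, function(r) paste(sites[r], collapse = "+"))
  tab <- table(key)
  clones <- data.frame(mutations = names(tab), reads = as.integer(tab),
                       stringsAsFactors = FALSE)
  if (!"" %in% clones$mutations)
    clones <- rbind(clones, data.frame(mutations = "", reads = 0L))
  clones$fraction <- clones$reads / n_inf
  clones <- clones[order(-clones$reads, clones$mutations), , drop = FALSE]
  rownames(clones) <- NULL
  structure(
    list(clones = clones, sites = sites, n_informative = n_inf,
         n_noninformative = nrow(haplotypes) - n_inf,
         phasing_available = TRUE),
    class = "clone_table")
}

# clone fraction mass carrying a given mutation (equals its VAF over
# informative reads, exactly)
.clone_vaf <- function(clone_table, label) {
  sets <- strsplit(clone_table$clones$mutations, "+", fixed = TRUE)
  has <- vapply(sets, function(s) label %in% s, TRUE)
  sum(clone_table$clones$fraction[has])
}

#' Do two mutations co-occur on the same molecules?
#'
#' Classifies the relationship of two phased mutations, with an explicit
#' noise floor — `max(2 reads, 0.2% of informative reads)` — so that
#' categorical statements ("never in isolation") are robust to rare chimeric
#' or error-corrupted reads: counts at or below the floor are treated as
#' zero.
#'
#' * `same_clone_only`: `b` never appears without `a`.
#' * `exclusive`: the double-mutant count is below the floor.
#' * `mixed`: both configurations exceed the floor.
#'
#' @param clone_table A [clonal_distribution()] result.
#' @param mutation_a,mutation_b Labels of two phased mutations.
#' @return List: `descriptor`, `counts` (named: `both`, `a_only`, `b_only`,
#'   `neither`), `noise_floor`.
#' @export
cooccurrence_test <- function(clone_table, mutation_a, mutation_b) {
  stopifnot(inherits(clone_table, "clone_table"))
  for (m in c(mutation_a, mutation_b))
    if (!m %in% clone_table$sites)
      stop("mutation '", m, "' was not phased in this sample", call. = FALSE)
  sets <- strsplit(clone_table$clones$mutations, "+", fixed = TRUE)
  has_a <- vapply(sets, function(s) mutation_a %in% s, TRUE)
  has_b <- vapply(sets, function(s) mutation_b %in% s, TRUE)
  reads <- clone_table$clones$reads
  counts <- c(both = sum(reads[has_a & has_b]),
              a_only = sum(reads[has_a & !has_b]),
              b_only = sum(reads[!has_a & has_b]),
              neither = sum(reads[!has_a & !has_b]))
  floor_n <- max(2, 0.002 * clone_table$n_informative)
  over <- function(x) x > floor_n
  descriptor <-
    if (!over(counts[["b_only"]])) "same_clone_only"
    else if (!over(counts[["both"]])) "exclusive"
    else "mixed"
  list(descriptor = descriptor, counts = counts, noise_floor = floor_n)
}

#' @export
print.clone_table <- function(x, width = 40, ...) {
  cat(sprintf("Clonal distribution over {%s} (%d informative, %d dropped)\n",
              paste(x$sites, collapse = ", "),
              x$n_informative, x$n_noninformative))
  if (!x$phasing_available) {
    cat("  phasing unavailable: no informative reads\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$clones))) {
    lab <- if (x$clones$mutations[i] == "") "wild-type"
           else x$clones$mutations[i]
    bar <- strrep("#", round(width * x$clones$fraction[i]))
    cat(sprintf("  %-28s %6d  %5.1f%% %s\n", lab, x$clones$reads[i],
                100 * x$clones$fraction[i], bar))
  }
  invisible(x)
}
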