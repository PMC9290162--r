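#' Specify a synthetic amplicon sample
#'
#' A simulation specification describes a sample as a mixture of clones,
#' each clone carrying a set of nucleotide substitutions at a stated
#' population fraction; any remaining fraction is the implicit wild-type
#' clone. The defaults emulate high-accuracy circular-consensus reads:
#' a small iid per-base substitution error rate, an even smaller indel
#' error rate, and a 50/50 strand orientation mixture.
#'
#' @param isoform_id Isoform (panel member) reads are generated from.
#' @param clones List of clones, each a list with `mutations` (character
#'   vector of amino-acid labels, or a list of `list(position=, alt=)` raw
#'   substitutions) and `fraction` in `[0, 1]`.
#' @param n_reads Number of reads to generate.
#' @param sub_error_rate Per-base substitution error rate (default 0.003).
#' @param indel_error_rate Per-base indel error rate (default 0.001; split
#'   evenly between single-base deletions and insertions).
#' @param reverse_fraction Probability a read is emitted reverse-complemented
#'   (default 0.5).
#' @param off_target_fraction Fraction of primer-free random-sequence reads
#'   (default 0).
#' @param seed Default random seed used when [simulate_reads()] is not given
#'   one explicitly.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(isoform_id, clones, n_reads,
                            sub_error_rate = 0.003, indel_error_rate = 0.001,
                            reverse_fraction = 0.5, off_target_fraction = 0,
                            seed = 1L) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  for (fld in c("sub_error_rate", "indel_error_rate")) {
    v <- get(fld)
    if (v < 0 || v > 0.1)
      stop(fld, " must lie in [0, 0.1]", call. = FALSE)
  }
  if (reverse_fraction < 0 || reverse_fraction > 1)
    stop("reverse_fraction must lie in [0, 1]", call. = FALSE)
  if (off_target_fraction < 0 || off_target_fraction >= 1)
    stop("off_target_fraction must lie in [0, 1)", call. = FALSE)
  fracs <- vapply(clones, function(cl) as.numeric(cl$fraction), 0)
  if (any(fracs < 0) || sum(fracs) > 1 + 1e-9)
    stop("clone fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  structure(
    list(isoform_id = isoform_id, clones = clones, n_reads = n_reads,
         sub_error_rate = sub_error_rate, indel_error_rate = indel_error_rate,
         reverse_fraction = reverse_fraction,
         off_target_fraction = off_target_fraction, seed = as.integer(seed)),
    class = "simulation_spec")
}

#' Load a simulation specification from YAML
#'
#' See `system.file("extdata", "scenarios", package = "lramp")` for shipped
#' examples, including the canonical multi-clone phasing scenario.
#'
#' @param path YAML file.
#' @param ... Overrides passed on to [simulation_spec()] (e.g. `n_reads`).
#' @return A `simulation_spec`.
#' @export
load_simulation_spec <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  cfg$clones <- lapply(cfg$clones, function(cl) {
    if (is.character(cl$mutations)) cl$mutations <- as.list(cl$mutations)
    cl
  })
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  do.call(simulation_spec, cfg)
}

#' Expected variant allele frequency of every mutation in a specification
#'
#' Each mutation's expected VAF is the sum of the fractions of the clones
#' that carry it.
#'
#' @param spec A [simulation_spec()].
#' @return Named numeric vector, one entry per mutation label.
#' @export
expected_vafs <- function(spec) {
  out <- numeric()
  for (cl in spec$clones) {
    for (mut in cl$mutations) {
      key <- if (is.character(mut)) mut else sprintf("%d%s", mut$position, mut$alt)
      out[key] <- (if (key %in% names(out)) out[[key]] else 0) + cl$fraction
    }
  }
  out
}

# deterministic largest-remainder apportionment of n items to fractions
.apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# resolve one clone's mutations to substitutions on the isoform:
# amino-acid labels pick the alternate codon with the fewest nucleotide
# changes from the reference codon (ties broken alphabetically)
.resolve_substitutions <- function(mutations, iso) {
  pos <- integer(); alt <- character()
  for (mut in mutations) {
    if (is.character(mut)) {
      km <- known_mutation(mut)
      cp <- codon_to_positions(iso, km$codon_number)
      ref_codon <- substr(iso$sequence, cp[1], cp[3])
      if (translate_codon(ref_codon) != km$ref_aa)
        stop("label ", mut, " does not match isoform '", iso$isoform_id,
             "' (reference codon ", ref_codon, ")", call. = FALSE)
      cand <- sort(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE == km$alt_aa])
      if (length(cand) == 0)
        stop("no codon encodes amino acid '", km$alt_aa, "'", call. = FALSE)
      dist <- vapply(cand, function(cd)
        sum(strsplit(cd, "")[[1]] != strsplit(ref_codon, "")[[1]]), 0L)
      alt_codon <- cand[which.min(dist)]   # sorted, so ties go alphabetical
      diff <- which(strsplit(alt_codon, "")[[1]] !=
                      strsplit(ref_codon, "")[[1]])
      pos <- c(pos, cp[diff])
      alt <- c(alt, strsplit(alt_codon, "")[[1]][diff])
    } else {
      if (is.null(mut$position) || is.null(mut$alt))
        stop("raw substitution needs 'position' and 'alt'", call. = FALSE)
      if (mut$position < 1 || mut$position > nchar(iso$sequence))
        stop("substitution position ", mut$position, " outside isoform",
             call. = FALSE)
      pos <- c(pos, as.integer(mut$position))
      alt <- c(alt, toupper(mut$alt))
    }
  }
  list(position = pos, alt = alt)
}

# run code under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic amplicon reads with known clone structure
#'
#' Reads are apportioned to clones deterministically by largest-remainder
#' rounding of the clone fractions (the realized clone composition equals the
#' specification exactly; residual stochasticity comes only from the error
#' process), then shuffled. Each read takes its clone's substitutions, iid
#' substitution errors (uniform over the three alternate bases), iid
#' single-base indel errors, both primers (error-free, since the pipeline
#' trims them before any base is counted), and is reverse-complemented with
#' probability `reverse_fraction`. Off-target reads are primer-free uniform
#' random sequences. A truth record carries the per-read clone identity and
#' the exact expected VAF of every mutation so tests never re-derive ground
#' truth from generator internals.
#'
#' @param spec A [simulation_spec()].
#' @param panel An [amplicon_panel()] whose isoform `spec$isoform_id` is the
#'   template.
#' @param fastq Optional path: write the reads as FASTQ.
#' @param truth Optional path: write the truth record as JSON.
#' @param seed Random seed (defaults to `spec$seed`).
#' @return List with `reads` (data frame: `read_id`, `sequence`,
#'   `qualities`) and `truth` (list: `clone_of_read`, `expected_vafs`,
#'   `clone_counts`, `seed`).
#' @export
simulate_reads <- function(spec, panel, fastq = NULL, truth = NULL,
                           seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(panel, "amplicon_panel"))
  iso <- panel$isoforms[[spec$isoform_id]]
  if (is.null(iso))
    stop("isoform '", spec$isoform_id, "' not in panel", call. = FALSE)
  subs <- lapply(spec$clones, function(cl)
    .resolve_substitutions(cl$mutations, iso))
  clone_ids <- vapply(seq_along(spec$clones), function(i) {
    muts <- spec$clones[[i]]$mutations
    if (length(muts) == 0) return(sprintf("clone%d", i))
    paste(vapply(muts, function(m)
      if (is.character(m)) m else sprintf("%d%s", m$position, m$alt), ""),
      collapse = "+")
  }, "")

  n <- spec$n_reads
  n_off <- .apportion(n, c(spec$off_target_fraction,
                           1 - spec$off_target_fraction))[1]
  n_on <- n - n_off
  fracs <- vapply(spec$clones, `[[`, 0, "fraction")
  counts <- .apportion(n_on, c(fracs, max(0, 1 - sum(fracs))))
  assignment <- c(rep(c(clone_ids, "wildtype"), counts),
                  rep("off_target", n_off))

  proto <- lapply(seq_along(spec$clones), function(i) {
    v <- strsplit(iso$sequence, "")[[1]]
    v[subs[[i]]$position] <- subs[[i]]$alt
    v
  })
  names(proto) <- clone_ids
  proto[["wildtype"]] <- strsplit(iso$sequence, "")[[1]]
  L <- nchar(iso$sequence)
  bases <- c("A", "C", "G", "T")
  # alt_tab[code, k]: the k-th alternative to base `code`
  alt_tab <- t(vapply(1:4, function(b) bases[-b], character(3)))
  fwd <- panel$forward_primer
  rc_rev <- .revcomp(panel$reverse_primer)

  out <- .with_seed(seed, {
    assignment <- assignment[sample.int(n)]
    n_sub <- stats::rbinom(n, L, spec$sub_error_rate)
    n_ind <- stats::rbinom(n, L, spec$indel_error_rate)
    revflag <- stats::runif(n) < spec$reverse_fraction
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (assignment[i] == "off_target") {
        seqs[i] <- paste(sample(bases, L, replace = TRUE), collapse = "")
        next
      }
      v <- proto[[assignment[i]]]
      if (n_sub[i] > 0) {
        p <- sample.int(L, n_sub[i])
        code <- match(v[p], bases)
        v[p] <- alt_tab[cbind(code, sample.int(3, n_sub[i], replace = TRUE))]
      }
      if (n_ind[i] > 0) {
        p <- sample.int(L, n_ind[i])
        del <- stats::runif(n_ind[i]) < 0.5
        if (any(del)) v[p[del]] <- ""
        if (any(!del))
          v[p[!del]] <- paste0(sample(bases, sum(!del), replace = TRUE),
                               v[p[!del]])
      }
      seqs[i] <- paste0(fwd, paste(v, collapse = ""), rc_rev)
    }
    off <- assignment == "off_target"
    flip <- revflag & !off
    if (any(flip)) seqs[flip] <- .revcomp(seqs[flip])
    list(assignment = assignment, seqs = seqs)
  })

  reads <- data.frame(
    read_id = sprintf("sim_%06d", seq_len(n)),
    sequence = out$seqs,
    qualities = strrep("I", nchar(out$seqs)),
    stringsAsFactors = FALSE)
  truth_rec <- list(
    isoform_id = spec$isoform_id,
    seed = seed,
    clone_of_read = as.list(setNames(out$assignment, reads$read_id)),
    clone_counts = as.list(table(out$assignment)),
    expected_vafs = as.list(expected_vafs(spec)))
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth))
    writeLines(jsonlite::toJSON(truth_rec, auto_unbox = TRUE, digits = NA),
               truth)
  list(reads = reads, truth = truth_rec)
}
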