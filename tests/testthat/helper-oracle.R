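# Independent full-matrix affine-gap DP oracle (score only) for the
# read-global / reference-end-gaps-free alignment shape. Deliberately written
# as a plain, slow, full dynamic program so it shares nothing with the
# package's banded implementation.
oracle_score <- function(read, ref, match = 2, mismatch = -4,
                         gap_open = -6, gap_extend = -1) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(f); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) for (j in 0:m) {
    jj <- j + 1
    if (j >= 1) {
      s <- if (r[i] == f[j] && r[i] != "N") match else mismatch
      prev <- if (i == 1) 0 else max(M[i, jj - 1], X[i, jj - 1], Y[i, jj - 1])
      M[i + 1, jj] <- if (prev > NEG / 2) prev + s else NEG
      a <- if (M[i + 1, jj - 1] > NEG / 2) M[i + 1, jj - 1] + gap_open else NEG
      b <- if (X[i + 1, jj - 1] > NEG / 2) X[i + 1, jj - 1] + gap_extend else NEG
      X[i + 1, jj] <- max(a, b)
    }
    ya <- if (i == 1) gap_open else
      if (M[i, jj] > NEG / 2) M[i, jj] + gap_open else NEG
    yb <- if (i == 1) NEG else
      if (Y[i, jj] > NEG / 2) Y[i, jj] + gap_extend else NEG
    Y[i + 1, jj] <- max(ya, yb)
  }
  max(M[n + 1, ], Y[n + 1, ])
}

# A deliberately small panel (66 bp reference) so constructed-read tests and
# property loops stay fast. Codons 240-259; M244, K247 and T250 carry real
# reference codons for the three catalogued test mutations.
tiny_isoform <- function() {
  codons <- rep("GCT", 20)
  names(codons) <- as.character(240:259)
  codons["244"] <- "ATG"
  codons["247"] <- "AAA"
  codons["250"] <- "ACT"
  isoform_reference("mini", paste0("GGT", paste(codons, collapse = ""), "TAG"),
                    cds_start = 4, codon_offset = 240,
                    description = "tiny synthetic test isoform")
}

tiny_panel <- function(known_mutations = c("M244V", "K247R", "T250I"), ...) {
  amplicon_panel(forward_primer = "GGATCCTAGGCA",
                 reverse_primer = "TTCAGGACCTGT",
                 isoforms = list(tiny_isoform()),
                 known_mutations = known_mutations,
                 name = "tiny-test-panel", ...)
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# construct a full raw read (with primers) for a panel isoform, with optional
# substitutions given as list(position =, alt =) in reference coordinates
make_read <- function(panel, subs = NULL, orientation = "forward",
                      isoform = 1, read_id = "r1") {
  iso <- panel$isoforms[[isoform]]
  v <- strsplit(iso$sequence, "")[[1]]
  for (s in subs) v[s$position] <- s$alt
  seqs <- paste0(panel$forward_primer, paste(v, collapse = ""),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(panel$reverse_primer))))
  if (orientation == "reverse")
    seqs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqs)))
  data.frame(read_id = read_id, sequence = seqs, stringsAsFactors = FALSE)
}

# n identical wild-type reads (or with shared substitutions)
make_reads <- function(panel, n, subs = NULL, orientation = "forward") {
  one <- make_read(panel, subs = subs, orientation = orientation)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             sequence = rep(one$sequence, n), stringsAsFactors = FALSE)
}
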