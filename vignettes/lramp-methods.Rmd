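---
title: "Methods: long-read amplicon mutation profiling with lramp"
author: "lramp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read amplicon mutation profiling with lramp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients treated for chronic myeloid leukemia (CML) with tyrosine kinase
inhibitors (TKIs) can develop resistance through point mutations in the
kinase domain of the BCR-ABL1 fusion transcript — T315I being the most
consequential. Conventional Sanger sequencing only detects variants above
roughly 15–20% allele frequency, so emerging resistant clones are seen
late. High-accuracy long reads (circular-consensus sequencing of a
full-length amplicon spanning the fusion transcript) change the problem in
two ways: individual molecules are read accurately enough that variants
down to a fraction of a percent are quantifiable, and each read spans every
mutation site at once, so determining which mutations co-occur on the same
molecule ("phasing") reduces to bookkeeping rather than statistical
inference.

`lramp` implements the complete analysis for one sample — from a FASTQ of
amplicon reads to a clinician-facing report — plus the surrounding
infrastructure: an append-only results store with query and report
commands, a two-method concordance analysis, and a synthetic read
simulator that provides ground truth for every stage.

## Pipeline model and assumptions

The pipeline is a fixed sequence of steps, each implemented as an exported
function so every stage can be exercised and tested in isolation:

1. **Primer filtering** (`filter_reads`). A read is kept only if the
   forward primer matches its 5' end and the reverse-complemented reverse
   primer its 3' end (or the same after reverse-complementing the read).
   Matching is *anchored Hamming comparison* over the terminal
   `nchar(primer)` bases with a configurable tolerance
   (`max_primer_mismatches`, default 2); `N` always counts as a mismatch.
   There is no fuzzy search inside the read: amplicon molecules carry their
   primers at the ends, and an anchored comparison is deterministic and
   fast. Kept reads are oriented to the reference strand and their primer
   spans trimmed, so primer-synthesis errors can never appear as variants.
2. **Isoform assignment** (`assign_reference`). Exon usage of the fusion
   transcript varies between patients, so the panel may carry several
   candidate isoform references. A seeded random subsample of reads
   (default cap 500) each votes for its best-scoring isoform under the
   shared alignment scheme; the winner becomes the sample's reference.
   Ties break by panel order and are flagged. Reads from minority isoforms
   are *not* discarded — they simply align to the chosen reference with a
   gap — because discarding them would silently change denominators.
3. **Alignment and pileup** (`align_reads`, `build_pileup`). Every kept
   read is aligned end-to-end against the reference with free reference
   end-gaps (the right shape for near-full-length amplicon reads), affine
   gap costs, and a deterministic traceback. Per reference position each
   read contributes one observation: a base, `N`, or a deletion; insertions
   go to a side table and never enter substitution counts. Deletions count
   toward coverage (the molecule did span the locus); `N` does not. Reads
   whose aligned span covers less than half the reference are set aside as
   partial — chimeric or truncated molecules would otherwise distort VAFs.
4. **Coverage QC** (`check_coverage`). Every reference position must be
   covered by at least `min_coverage` reads (default 100). On failure the
   analysis *aborts* with a distinct status: reporting "negative" at an
   under-covered site would be clinically unsafe, so a failed sample gets a
   QC banner and no calls at all.
5. **Variant calling** (`scan_de_novo`, `call_known`). The de novo scan
   reports any (position, alternate base) with at least `min_alt_reads`
   supporting reads (default 3) and nucleotide-level VAF at or above the
   positive cutoff. Catalogued mutations are counted per read at the
   *codon* level: a read supports T315I only if its translated codon at
   position 315 is isoleucine. This resolves distinct substitutions at one
   codon (F359I vs F359V vs F359C) that nucleotide counting conflates.
   Every catalogued mutation appears in the output, negatives included.
6. **Clonal phasing** (`extract_haplotypes`, `clonal_distribution`,
   `cooccurrence_test`). When two or more positive mutations co-occur,
   each read is genotyped at every positive site (alt / ref / missing),
   reads with any missing site are set aside, and the rest are grouped by
   exact mutation set. Fractions are taken over informative reads, which
   makes the identity "sum of fractions of clones carrying m = VAF of m
   over informative reads" hold exactly, not approximately.
7. **Persistence and reporting** (`store_result`, `query_samples`,
   `render_report`). Records append to a JSON-Lines store, are never
   overwritten, and render deterministically to text or HTML.

## Thresholds and boundary semantics

Three numbers drive clinical interpretation, all configurable on the
panel and all with explicit boundary semantics:

| parameter         | default | units    | boundary |
|-------------------|---------|----------|----------|
| `positive_cutoff` | 0.005   | fraction | inclusive: VAF ≥ 0.5% is positive |
| `clinical_cutoff` | 0.01    | fraction | strict: only VAF > 1% is clinically reportable |
| `min_coverage`    | 100     | reads    | inclusive: coverage ≥ 100 passes |
| `min_alt_reads`   | 3       | reads    | absolute floor on supporting reads |

The 0.5% cutoff is inclusive because detection was validated down to that
level; the 1% clinical bound is strict because only variants *above* it
are considered actionable. `min_alt_reads` protects low-coverage runs
where a percentage cutoff alone would let one or two error reads through.

## The VAF estimator

For a catalogued mutation, the denominator is the number of reads whose
codon translates to the reference amino acid *or to a catalogued alternate*
at that codon; reads whose codon is interrupted by a deletion or `N`, and
reads whose translation matches no catalogued allele (overwhelmingly
substitution-error artifacts), are excluded and reported separately. The
alternative — dividing by all gap-free codons — deflates every VAF by
roughly twice the per-base error rate, a bias of about −0.7 percentage
points at VAF 97% under the default error model, while inflating nothing.
Excluding uninterpretable codons removes that bias symmetrically; the
estimator is then unbiased across the dynamic range (a property test
checks mean recovery at VAFs 0.5%–50%, five replicates each of 4000 reads,
against twice the single-run binomial standard error).

One characteristic worth knowing: the codon-level error background of a
mutation is approximately `sub_error_rate / 3 × k`, where `k` is the
number of single-nucleotide paths from the reference codon to a codon for
the alternate amino acid. For most panel mutations `k = 1` (~0.1%
background at the default error rate), but e.g. M472I has `k = 3` (ATG to
ATA/ATT/ATC, ~0.3%). The 0.5% positive cutoff sits above all of these in
expectation, but at coverage of only a few hundred reads Poisson noise on
a `k = 3` codon can occasionally cross it — one reason the QC floor and
the clinical 1% bound exist.

## Alignment scoring and numerics

The aligner scores match +2, mismatch −4, gap open −6 (charged on the
first gapped base), gap extension −1. The shape is "glocal": the read is
consumed in full, reference overhangs are free. Traceback ties resolve
deterministically: match/mismatch over deletion over insertion, and the
leftmost end position on equal end scores. The implementation is a banded
dynamic program in C++; the band is sized adaptively as the read/reference
length difference plus 32, which covers any start offset of a truncated
read plus indel wiggle, and a zero band width forces the full matrix. The
tests hold the banded implementation to *exact* score equality against an
independent full-matrix DP oracle (200 random pairs) and against
`Biostrings::pairwiseAlignment` in the equivalent `global-local`
parameterization.

## The simulator: what it emulates and what it does not

`simulate_reads` generates a sample as a mixture of clones, each a set of
mutations (amino-acid labels resolved to the minimal-nucleotide-change
codon, ties alphabetical) at a stated fraction. Defaults describe
high-accuracy circular-consensus reads: substitution errors at 0.003 per
base (uniform over the three alternates), indel errors at 0.001 per base
(half single-base deletions, half insertions), both strands equally
likely, no off-target reads unless requested.

Two deliberate design choices:

* **Clone mixing is exact.** Reads are apportioned to clones by
  largest-remainder rounding of the fractions and then shuffled, so the
  realized clone composition equals the specification and the only
  stochasticity is the error process. A simulated detection-limit
  experiment then measures the pipeline's behaviour at the stated VAF,
  not at the stated VAF plus binomial sampling noise of the ground truth
  itself.
* **Errors are applied to the insert only.** Primer bases are attached
  error-free, because the pipeline trims them before any base is counted;
  modelling primer errors would only re-test the trimming code.

The simulator does *not* model CCS error structure (quality values,
homopolymer bias, chimeras, PCR bias). Passing tests therefore demonstrate
correct behaviour of the analysis under an idealized iid error model at
realistic rates — they do not certify performance on any particular
instrument's error profile. Real validation requires real control
samples.

Problem sizes used by the test suite were chosen to exercise the assay's
operating point: detection-limit and phasing checks run 20 replicates of
10,000 reads (roughly the coverage the assay produces per sample);
structural unit tests use a deliberately small 66-bp test panel so that
constructed-read cases stay readable and fast.

## Concordance counting

`compare_call_sets` compares a VAF-free reference call set (Sanger-style)
against a VAF-bearing one per sample: reference mutations missed, extra
mutations found, extras above the clinical cutoff, and per-sample classes
(both negative / full agreement / superset / other). Labels match as
strings, with one wrinkle: a codon-only label such as `E255` (alternate
amino acid not stated by the reporting method) matches any label at the
same codon, and counts as an extra only when the other side has no call at
that codon. The packaged 39-sample validation fixture transcribes a real
two-method comparison, including one such ambiguous label, which is kept
as `E255` rather than guessed. A nomenclature note: one figure source for
the nested-clone sample prints the rare variant as "K257R" while the
table and text use K247R; the fixture follows the table.

## Degenerate inputs and tie-breaks

* Empty FASTQ: zero reads in, a `qc_failed` record out — never an error.
* Single-isoform panels skip scoring entirely.
* Exact vote ties: first isoform in panel order wins, `tie` flag set.
* Codons interrupted by deletion/N: `missing` in phasing, excluded from
  VAF denominators.
* Zero informative reads in phasing: `phasing_available = FALSE`, not an
  exception.
* Co-occurrence statements use an explicit noise floor,
  `max(2, 0.2% of informative reads)`: categorical claims like "never in
  isolation" are made only above it.

## Known limitations

* Substitutions only: no indel or structural-variant calling (insertions
  and deletions are tabulated but not called).
* No quality-weighted counting; CCS reads are treated as consensus truth.
* Isoform candidates must be supplied in the panel; there is no de novo
  isoform discovery.
* Single-sample scope: no longitudinal clone tracking across records
  beyond what the store's query interface allows.
* The packaged demo references are synthetic stand-ins engineered so all
  catalogued mutations are representable; real deployments must supply
  their own isoform FASTA and codon-numbering metadata.
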