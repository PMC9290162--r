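# lramp — long-read amplicon mutation profiling

`lramp` is an R package implementing the complete analysis pipeline for
**TKI-resistance mutation screening in BCR-ABL1 by high-accuracy long-read
amplicon sequencing**. Patients treated for chronic myeloid leukemia with
tyrosine kinase inhibitors develop resistance through kinase-domain point
mutations (T315I, Y253H, E255K/V, ...). Sanger sequencing only sees
variants above ~15–20% allele frequency; full-length circular-consensus
amplicon reads detect them down to 0.5% *and*, because every read spans
every mutation site, resolve which mutations co-occur on the same
molecules.

The pipeline, from a FASTQ of amplicon reads to a clinician-facing report:

1. keep only reads carrying both expected primers (anchored Hamming match,
   ≤ 2 mismatches), oriented to the reference strand and primer-trimmed;
2. assign the dominant transcript isoform by per-read best-score voting and
   fix it as the sample reference;
3. align every read (banded semi-global affine-gap DP: match +2, mismatch
   −4, gap open −6, extend −1) and accumulate a per-position pileup;
4. abort unless every position is covered by ≥ 100 reads (a negative call
   at an under-covered site would be clinically unsafe);
5. call variants: de novo substitution scan plus per-read, codon-level
   VAFs for every catalogued mutation — VAF(m) = reads whose translated
   codon equals m's alternate amino acid / reads with an interpretable
   allele at that codon; ≥ 0.5% is *positive*, > 1% *clinically
   reportable*, with an absolute floor of 3 supporting reads;
6. when ≥ 2 positive mutations co-occur, group reads by their exact
   mutation set into clones (per-read phasing, no inference needed);
7. append the record to a JSON-Lines results store with query/report
   commands.

It also ships a two-method concordance module (Sanger-style call sets vs
VAF-bearing call sets, with the packaged 39-sample validation fixture) and
a synthetic read simulator with exact clone apportionment that provides
ground truth for every stage.

## Worked example

Simulate the canonical nested-clone sample — L273M (56%) and T315I (41%)
in distinct molecules, K247R (3%) only ever on the T315I background — and
run the full pipeline on it:

```r
library(lramp)

panel <- demo_panel()   # packaged demo panel: 2 isoforms, 15 mutations
spec  <- load_simulation_spec(
  system.file("extdata", "scenarios", "fig3.yaml", package = "lramp"))
sim   <- simulate_reads(spec, panel, seed = 11)
rec   <- run_sample(sim$reads, panel, sample_id = "demo", seed = 11)
cat(render_report(rec, "text"))
```

```
Mutation report — sample demo
run: 2026-09-23T02:49:10Z | pipeline 0.1.0 | panel demo-bcr-abl1 (c2be212a2c91)
isoform: e14a2
QC: passed (min coverage 9978, threshold 100)

label    status           VAF(%)  alt reads  codon coverage
M244V    negative            0.1          7  9985
K247R    clinically_reportable        3.1        302  9974
Y253H    negative            0.1         13  9992
E255K    negative            0.1         14  9980
E255V    negative            0.1         10  9980
L273M    clinically_reportable       55.7       5533  9982
D276G    negative            0.1         11  9986
L298V    negative            0.1          9  9983
T315I    clinically_reportable       44.0       4363  9980
F359C    negative            0.1          7  9989
F359I    negative            0.1          7  9989
F359V    negative            0.1         11  9989
H396R    negative            0.1         10  9978
E450G    negative            0.1         12  9993
M472I    negative            0.3         31  9984

clonal distribution over {K247R, L273M, T315I} (9733 informative reads):
  L273M                          5411 reads   55.6%  ######################
  T315I                          3990 reads   41.0%  ################
  K247R+T315I                     293 reads    3.0%  #
  wild-type                        21 reads    0.2%  
  L273M+T315I                      12 reads    0.1%  
  K247R+L273M                       5 reads    0.1%  
  K247R                             1 reads    0.0%
```

Reading it: the three simulated mutations are recovered at their true
fractions (K247R 3.1% vs 3%, L273M 55.7% vs 56%, T315I 44.0% vs 44%); all
twelve other catalogued mutations are explicitly asserted negative, with
their ~0.1–0.3% sequencing-error background well below the 0.5% cutoff;
and the clone table shows K247R occurring only together with T315I while
L273M and T315I sit in distinct molecules:

```r
ct <- structure(rec$clones, class = "clone_table")
cooccurrence_test(ct, "T315I", "K247R")$descriptor   # "same_clone_only"
cooccurrence_test(ct, "L273M", "T315I")$descriptor   # "exclusive"
```

The packaged validation fixture reproduces the published two-method
comparison:

```r
cs <- table1_callsets()
compare_call_sets(cs[cs$method == "sanger", ], cs[cs$method == "lrsms", ])
#> Concordance over 39 samples
#>   reference-method mutations: 17 (missed by comparator: 0)
#>   comparator-only mutations:  16 (8 above the clinical cutoff)
#>   samples: 21 double-negative, 18 with mutations (5 full agreement, 13 comparator found more)
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "lramp", package = "lramp")` with subcommands
`run`, `simulate`, `compare`, `query` and `report` (exit codes: 0 ok,
2 usage/config error, 3 QC failure).

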