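test_that("classification boundaries are inclusive at 0.5% and strict at 1%", {
  panel <- tiny_panel()
  expect_identical(classify(0.004, panel), "negative")
  expect_identical(classify(0.005, panel), "positive")    # >= at the cutoff
  expect_identical(classify(0.008, panel), "positive")
  expect_identical(classify(0.010, panel), "positive")    # 1% itself not reportable
  expect_identical(classify(0.0101, panel), "clinically_reportable")
  expect_identical(classify(0.021, panel), "clinically_reportable")
  # monotone over a grid
  grid <- seq(0, 1, by = 0.001)
  ranks <- match(classify(grid, panel),
                 c("negative", "positive", "clinically_reportable"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("error-free wild-type samples produce no de novo calls and all-negative known results", {
  panel <- tiny_panel()
  ref <- panel$isoforms[[1]]
  spec <- simulation_spec("mini", list(), n_reads = 200,
                          sub_error_rate = 0, indel_error_rate = 0)
  sim <- simulate_reads(spec, panel, seed = 31)
  kept <- filter_reads(sim$reads, panel)$kept
  al <- align_reads(kept, ref)
  pp <- build_pileup(al)
  expect_identical(nrow(scan_de_novo(pp, ref, panel)), 0L)
  kn <- call_known(al, ref, panel)
  # every panel mutation reported exactly once, negatives included
  expect_setequal(kn$label, c("M244V", "K247R", "T250I"))
  expect_true(all(kn$status == "negative"))
  expect_true(all(kn$vaf == 0))
  expect_identical(kn$codon_coverage, rep(200L, 3))
})

test_that("a spiked mutation is called at its spec fraction with the right label", {
  panel <- tiny_panel()
  ref <- panel$isoforms[[1]]
  spec <- simulation_spec("mini",
                          list(list(mutations = "T250I", fraction = 0.05)),
                          n_reads = 2000)
  sim <- simulate_reads(spec, panel, seed = 17)
  kept <- filter_reads(sim$reads, panel)$kept
  al <- align_reads(kept, ref)
  pp <- build_pileup(al)

  kn <- call_known(al, ref, panel)
  t250 <- kn[kn$label == "T250I", ]
  expect_identical(t250$status, "clinically_reportable")
  expect_lt(abs(t250$vaf - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_true(all(kn$status[kn$label != "T250I"] == "negative"))

  # the underlying nucleotide site is found by the de novo scan with the
  # same amino-acid label (direction agreement between steps 4 and 5)
  dn <- scan_de_novo(pp, ref, panel)
  expect_true("T250I" %in% dn$aa_label)
  hit <- dn[which(dn$aa_label == "T250I"), ]
  expect_true(hit$known)
  expect_identical(hit$position, codon_to_positions(ref, 250)[2])
  expect_identical(hit$ref_base, "C"); expect_identical(hit$alt_base, "T")
})

test_that("codon-level counting distinguishes alternate alleles at one codon", {
  panel <- amplicon_panel("GGATCCTAGGCA", "TTCAGGACCTGT",
                          list(tiny_isoform()),
                          known_mutations = c("T250I", "T250P"),
                          name = "two-allele")
  ref <- panel$isoforms[[1]]
  cp <- codon_to_positions(ref, 250)          # ref codon ACT
  ile <- make_reads(panel, 30, subs = list(list(position = cp[2], alt = "T")))
  pro <- make_reads(panel, 10, subs = list(list(position = cp[1], alt = "C")))
  pro$read_id <- paste0("p", seq_len(10))
  wt <- make_reads(panel, 60)
  wt$read_id <- paste0("w", seq_len(60))
  kept <- filter_reads(rbind(ile, pro, wt), panel)$kept
  kn <- call_known(align_reads(kept, ref), ref, panel)
  expect_identical(kn$supporting_reads[kn$label == "T250I"], 30L)
  expect_identical(kn$supporting_reads[kn$label == "T250P"], 10L)
  expect_equal(kn$vaf[kn$label == "T250I"], 0.30)
  expect_equal(kn$vaf[kn$label == "T250P"], 0.10)
})

test_that("codons interrupted by deletions drop out of the denominator", {
  panel <- tiny_panel()
  ref <- panel$isoforms[[1]]
  cp <- codon_to_positions(ref, 250)
  ile <- make_reads(panel, 5, subs = list(list(position = cp[2], alt = "T")))
  # 10 reads whose T250 codon is disrupted by deleting its middle base
  v <- strsplit(ref$sequence, "")[[1]][-cp[2]]
  gap <- data.frame(read_id = sprintf("g%02d", 1:10),
                    sequence = paste0(panel$forward_primer,
                                      paste(v, collapse = ""),
                                      .revcomp_chr(panel$reverse_primer)))
  wt <- make_reads(panel, 85)
  wt$read_id <- paste0("w", seq_len(85))
  kept <- filter_reads(rbind(ile, gap, wt), panel)$kept
  kn <- call_known(align_reads(kept, ref), ref, panel)
  t250 <- kn[kn$label == "T250I", ]
  expect_identical(t250$codon_coverage, 90L)     # 100 reads - 10 disrupted
  expect_identical(t250$supporting_reads, 5L)
  expect_equal(t250$vaf, 5 / 90)
})

test_that("the absolute alt-read floor suppresses sub-threshold support", {
  panel <- tiny_panel(min_alt_reads = 3)
  ref <- panel$isoforms[[1]]
  cp <- codon_to_positions(ref, 250)
  two <- make_reads(panel, 2, subs = list(list(position = cp[2], alt = "T")))
  wt <- make_reads(panel, 148)
  wt$read_id <- paste0("w", seq_len(148))
  kept <- filter_reads(rbind(two, wt), panel)$kept
  al <- align_reads(kept, ref)
  kn <- call_known(al, ref, panel)
  # 2/150 = 1.3% would be reportable by VAF, but 2 reads are below the floor
  expect_identical(kn$status[kn$label == "T250I"], "negative")
  expect_identical(nrow(scan_de_novo(build_pileup(al), ref, panel)), 0L)
})

test_that("the VAF estimator is unbiased across the dynamic range", {
  panel <- tiny_panel()
  ref <- panel$isoforms[[1]]
  n_reads <- 4000
  for (f in c(0.005, 0.01, 0.05, 0.5)) {
    spec <- simulation_spec("mini",
                            list(list(mutations = "T250I", fraction = f)),
                            n_reads = n_reads)
    vafs <- vapply(1:5, function(s) {
      sim <- simulate_reads(spec, panel, seed = 1000 + s)
      kept <- filter_reads(sim$reads, panel)$kept
      kn <- call_known(align_reads(kept, ref), ref, panel)
      kn$vaf[kn$label == "T250I"]
    }, 0)
    expect_lt(abs(mean(vafs) - f), 2 * sqrt(f * (1 - f) / n_reads))
  }
})
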