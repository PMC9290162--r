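test_that("per-read genotypes code alt, ref and missing correctly", {
  panel <- tiny_panel()
  ref <- panel$isoforms[[1]]
  cp244 <- codon_to_positions(ref, 244)   # ATG -> GTG is M244V
  cp247 <- codon_to_positions(ref, 247)   # AAA -> AGA is K247R

  both <- make_read(panel, subs = list(list(position = cp244[1], alt = "G"),
                                       list(position = cp247[2], alt = "G")),
                    read_id = "both")
  one <- make_read(panel, subs = list(list(position = cp244[1], alt = "G")),
                   read_id = "one")
  wt <- make_read(panel, read_id = "wt")
  # a read with the K247 codon deleted is missing at that site
  v <- strsplit(ref$sequence, "")[[1]][-cp247]
  gap <- data.frame(read_id = "gap",
                    sequence = paste0(panel$forward_primer,
                                      paste(v, collapse = ""),
                                      .revcomp_chr(panel$reverse_primer)))
  kept <- filter_reads(rbind(both, one, wt, gap), panel)$kept
  al <- align_reads(kept, ref)
  h <- extract_haplotypes(al, ref, c("M244V", "K247R"))
  expect_identical(h["both", ], c(M244V = "alt", K247R = "alt"))
  expect_identical(h["one", ], c(M244V = "alt", K247R = "ref"))
  expect_identical(h["wt", ], c(M244V = "ref", K247R = "ref"))
  expect_identical(h["gap", "K247R"], "missing")
  expect_error(extract_haplotypes(al, ref, "M244V"), "at least 2")
})

test_that("clone aggregation groups exact mutation sets and always lists wild type", {
  h <- rbind(c("alt", "alt"), c("alt", "alt"), c("alt", "ref"),
             c("ref", "ref"), c("missing", "alt"))
  colnames(h) <- c("A100B", "C200D")
  rownames(h) <- sprintf("r%d", 1:5)
  ct <- clonal_distribution(h)
  expect_identical(ct$n_informative, 4L)
  expect_identical(ct$n_noninformative, 1L)
  cl <- ct$clones
  expect_identical(cl$reads[cl$mutations == "A100B+C200D"], 2L)
  expect_identical(cl$reads[cl$mutations == "A100B"], 1L)
  expect_identical(cl$reads[cl$mutations == ""], 1L)
  expect_equal(sum(cl$fraction), 1)

  # all wild type: single clone with fraction 1
  hwt <- matrix("ref", 3, 2, dimnames = list(NULL, c("A100B", "C200D")))
  ctwt <- clonal_distribution(hwt)
  expect_identical(ctwt$clones$mutations, "")
  expect_equal(ctwt$clones$fraction, 1)

  # no informative reads: phasing unavailable, not an error
  hmiss <- matrix("missing", 2, 2, dimnames = list(NULL, c("A100B", "C200D")))
  expect_false(clonal_distribution(hmiss)$phasing_available)
})

test_that("clone fractions reproduce each mutation's informative-read VAF exactly", {
  panel <- tiny_panel()
  ref <- panel$isoforms[[1]]
  spec <- simulation_spec("mini", list(
    list(mutations = "M244V", fraction = 0.5),
    list(mutations = "T250I", fraction = 0.3),
    list(mutations = c("T250I", "K247R"), fraction = 0.05)), n_reads = 1500)
  sim <- simulate_reads(spec, panel, seed = 77)
  kept <- filter_reads(sim$reads, panel)$kept
  al <- align_reads(kept, ref)
  h <- extract_haplotypes(al, ref, c("M244V", "K247R", "T250I"))
  ct <- clonal_distribution(h)
  informative <- h[rowSums(h == "missing") == 0, , drop = FALSE]
  for (m in colnames(h)) {
    vaf_inf <- mean(informative[, m] == "alt")
    mass <- sum(ct$clones$fraction[
      vapply(strsplit(ct$clones$mutations, "+", fixed = TRUE),
             function(s) m %in% s, TRUE)])
    expect_equal(mass, vaf_inf, tolerance = 1e-9)
  }
})

test_that("merging haplotype sets is equivalent to summing clone counts", {
  set.seed(12)
  mk <- function(n) {
    h <- matrix(sample(c("ref", "alt", "missing"), 2 * n, TRUE,
                       prob = c(0.6, 0.3, 0.1)), ncol = 2,
                dimnames = list(NULL, c("A100B", "C200D")))
    h
  }
  a <- mk(200); b <- mk(150)
  ca <- clonal_distribution(a)$clones
  cb <- clonal_distribution(b)$clones
  cab <- clonal_distribution(rbind(a, b))$clones
  for (muts in cab$mutations) {
    na <- if (muts %in% ca$mutations) ca$reads[ca$mutations == muts] else 0L
    nb <- if (muts %in% cb$mutations) cb$reads[cb$mutations == muts] else 0L
    expect_identical(cab$reads[cab$mutations == muts], na + nb)
  }
})

test_that("co-occurrence classification applies the noise floor", {
  mk_ct <- function(counts) {
    clones <- data.frame(mutations = names(counts),
                         reads = as.integer(counts))
    clones$fraction <- clones$reads / sum(clones$reads)
    structure(list(clones = clones,
                   sites = c("A100B", "C200D"),
                   n_informative = sum(clones$reads),
                   n_noninformative = 0L, phasing_available = TRUE),
              class = "clone_table")
  }
  # nested: second mutation only ever with the first
  ct <- mk_ct(setNames(c(500, 40, 460), c("A100B", "A100B+C200D", "")))
  r <- cooccurrence_test(ct, "A100B", "C200D")
  expect_identical(r$descriptor, "same_clone_only")
  expect_identical(unname(r$counts["both"]), 40L)

  # mutually exclusive
  ct <- mk_ct(setNames(c(300, 300, 400), c("A100B", "C200D", "")))
  expect_identical(cooccurrence_test(ct, "A100B", "C200D")$descriptor,
                   "exclusive")

  # a single stray double-mutant read stays below the floor
  ct <- mk_ct(setNames(c(300, 300, 1, 398),
                       c("A100B", "C200D", "A100B+C200D", "")))
  expect_identical(cooccurrence_test(ct, "A100B", "C200D")$descriptor,
                   "exclusive")

  # genuinely mixed
  ct <- mk_ct(setNames(c(300, 300, 100, 300),
                       c("A100B", "C200D", "A100B+C200D", "")))
  expect_identical(cooccurrence_test(ct, "A100B", "C200D")$descriptor,
                   "mixed")

  expect_error(cooccurrence_test(ct, "A100B", "X999Y"), "not phased")
})
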