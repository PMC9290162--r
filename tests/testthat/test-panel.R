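test_that("codon arithmetic maps protein numbering to reference positions", {
  iso <- isoform_reference("x", strrep("ACT", 12), cds_start = 1,
                           codon_offset = 1)
  expect_identical(codon_to_positions(iso, 1), 1:3)

  iso2 <- isoform_reference("y", paste0(strrep("G", 9), strrep("ACT", 10)),
                            cds_start = 10, codon_offset = 240)
  expect_identical(codon_to_positions(iso2, 244), 22:24)
  expect_error(codon_to_positions(iso2, 999), "outside")
  expect_error(codon_to_positions(iso2, 239), "outside")

  # strictly monotone with step 3
  starts <- vapply(240:248, function(cn) codon_to_positions(iso2, cn)[1], 0L)
  expect_identical(diff(starts), rep(3L, 8))
})

test_that("codon translation follows the standard genetic code", {
  expect_identical(translate_codon("ACT"), "T")
  expect_identical(translate_codon("ATT"), "I")
  expect_identical(translate_codon(c("TAA", "ATG")), c("*", "M"))
  # ambiguous bases give the undefined marker, never an error
  expect_identical(translate_codon("ANT"), "X")
})

test_that("mutation labels parse and validate", {
  m <- known_mutation("T315I")
  expect_identical(m$ref_aa, "T")
  expect_identical(m$codon_number, 315L)
  expect_identical(m$alt_aa, "I")
  expect_error(known_mutation("T315T"), "differ")
  expect_error(known_mutation("315I"), "malformed")
})

test_that("panel construction enforces its invariants", {
  expect_error(tiny_panel(positive_cutoff = 0.02, clinical_cutoff = 0.01),
               "positive_cutoff")
  expect_error(
    amplicon_panel("ACGTACGTACGT", "SHORT", list(tiny_isoform())),
    "reverse_primer")
  expect_error(
    amplicon_panel("ACGTACGTACGT", "TGCATGCATGCA",
                   list(tiny_isoform(), tiny_isoform())),
    "unique")
  # self-consistency: reference codon must translate to the stated ref AA
  expect_error(tiny_panel(known_mutations = "W250I"), "inconsistency")
  # codon not spanned by any isoform
  expect_error(tiny_panel(known_mutations = "T999I"), "inconsistency")
})

test_that("a minimal config loads with defaults applied", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "forward_primer: GGATCCTAGGCA",
    "reverse_primer: TTCAGGACCTGT",
    "isoforms:",
    "  - isoform_id: mini",
    "    cds_start: 4",
    "    codon_offset: 240",
    paste0("    sequence: ", tiny_isoform()$sequence)), cfg)
  panel <- load_panel(cfg)
  expect_identical(panel$positive_cutoff, 0.005)
  expect_identical(panel$clinical_cutoff, 0.01)
  expect_identical(panel$min_coverage, 100L)
  expect_identical(panel$max_primer_mismatches, 2L)
  expect_length(panel$known_mutations, 0)

  writeLines(c(readLines(cfg),
               "positive_cutoff: 0.02", "clinical_cutoff: 0.01"), cfg)
  expect_error(load_panel(cfg), "positive_cutoff")
  expect_error(load_panel(tempfile()), "not found")
})

test_that("isoform sequences can be supplied via FASTA", {
  dir <- tempfile(); dir.create(dir)
  fa <- Biostrings::DNAStringSet(tiny_isoform()$sequence)
  names(fa) <- "mini"
  Biostrings::writeXStringSet(fa, file.path(dir, "ref.fa"))
  cfg <- file.path(dir, "panel.yaml")
  writeLines(c(
    "forward_primer: GGATCCTAGGCA",
    "reverse_primer: TTCAGGACCTGT",
    "known_mutations: [M244V]",
    "isoforms:",
    "  - isoform_id: mini",
    "    cds_start: 4",
    "    codon_offset: 240",
    "    fasta: ref.fa"), cfg)
  panel <- load_panel(cfg)
  expect_identical(panel$isoforms$mini$sequence, tiny_isoform()$sequence)
})

test_that("the packaged demo panel loads with 15 self-consistent mutations", {
  panel <- demo_panel()
  labels <- vapply(panel$known_mutations, `[[`, "", "label")
  expect_setequal(labels, c("T315I", "Y253H", "E255K", "E255V", "F359C",
                            "F359I", "F359V", "M244V", "K247R", "L273M",
                            "D276G", "L298V", "H396R", "E450G", "M472I"))
  expect_length(labels, 15)
  expect_named(panel$isoforms, c("e14a2", "e13a2"))
  # the alternative isoform is the dominant one minus a 74-base 5' block
  expect_identical(nchar(panel$isoforms$e14a2$sequence) -
                     nchar(panel$isoforms$e13a2$sequence), 74L)
  # both isoforms agree on every catalogued codon (checked at load, but the
  # translation identity is worth asserting directly)
  for (m in panel$known_mutations) {
    for (iso in panel$isoforms) {
      cp <- codon_to_positions(iso, m$codon_number)
      expect_identical(
        translate_codon(substr(iso$sequence, cp[1], cp[3])), m$ref_aa)
    }
  }
})
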