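# build a minimal stored-style record from a list of (label, vaf%) calls,
# mirroring what run_sample produces for the fields the store and query use
fixture_record <- function(sample_id, calls, panel, timestamp) {
  labels <- vapply(panel$known_mutations, `[[`, "", "label")
  vaf <- setNames(rep(0, length(labels)), labels)
  for (nm in names(calls)) if (nm %in% labels) vaf[nm] <- calls[[nm]] / 100
  kr <- data.frame(label = labels, vaf = unname(vaf),
                   supporting_reads = as.integer(round(10000 * unname(vaf))),
                   codon_coverage = 10000L,
                   status = classify(unname(vaf), panel),
                   stringsAsFactors = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 run_timestamp = timestamp, status = "ok",
                 isoform_id = "e14a2", known_results = kr,
                 de_novo = NULL, clones = NULL,
                 pipeline_version = "0.0.0", panel_name = panel$name,
                 panel_hash = panel$panel_hash),
            class = "sample_record")
}

test_that("the store appends, round-trips and warns on exact duplicates", {
  panel <- tiny_panel()
  store <- tempfile(fileext = ".jsonl")
  rec <- fixture_record("s1", list(T250I = 12.5), panel,
                        "2024-01-02T03:04:05Z")
  id1 <- store_result(rec, store)
  back <- fetch_result(store, id1)
  expect_identical(back$sample_id, "s1")
  expect_identical(back$known_results$label, rec$known_results$label)
  expect_equal(back$known_results$vaf, rec$known_results$vaf)
  expect_identical(back$run_timestamp, rec$run_timestamp)

  # re-analysis appends a distinct record
  rec2 <- fixture_record("s1", list(T250I = 13.0), panel,
                         "2024-02-02T03:04:05Z")
  id2 <- store_result(rec2, store)
  expect_false(identical(id1, id2))
  expect_length(read_store(store), 2)

  # identical payload: stored, but with a warning
  expect_warning(store_result(rec, store), "identical")
  expect_length(read_store(store), 3)
  expect_error(fetch_result(store, "r999999"), "no record")
})

test_that("query filters by sample, mutation, status and date", {
  panel <- demo_panel()
  t1 <- table1_callsets()
  lr <- t1[t1$method == "lrsms" & t1$label != "-", ]
  store <- tempfile(fileext = ".jsonl")
  for (s in unique(t1$sample)) {
    rows <- lr[lr$sample == s, ]
    calls <- setNames(as.list(rows$vaf_percent), rows$label)
    calls <- calls[names(calls) != "E255"]   # codon-ambiguous, not in panel
    store_result(fixture_record(s, calls, panel,
                                sprintf("2024-01-%02dT00:00:00Z",
                                        as.integer(s) %% 28 + 1)), store)
  }
  all <- query_samples(store)
  expect_identical(nrow(all), 39L)
  expect_identical(all$sample_id, as.character(sort(as.integer(all$sample_id))))

  # clinically reportable T315I: the well-known positive set
  hits <- query_samples(store, mutation = "T315I",
                        min_status = "clinically_reportable")
  expect_identical(hits$sample_id, c("1", "2", "10", "12", "14", "15", "16",
                                     "24"))
  # at full sensitivity sample 26 (0.6%) joins
  hits2 <- query_samples(store, mutation = "T315I", min_status = "positive")
  expect_identical(hits2$sample_id, c("1", "2", "10", "12", "14", "15", "16",
                                      "24", "26"))
  expect_identical(nrow(query_samples(store, mutation = "Z999Z")), 0L)
  expect_identical(nrow(query_samples(store, sample_id = "14")), 1L)
  expect_identical(
    nrow(query_samples(store, from = "2024-01-10", to = "2024-01-12")),
    sum(vapply(read_store(store), function(r)
      r$run_timestamp >= "2024-01-10" && r$run_timestamp <= "2024-01-12",
      TRUE)))
})

test_that("reports list every catalogued mutation and render deterministically", {
  panel <- demo_panel()
  rec <- fixture_record("fig2b", list(T315I = 45.0, F359C = 3.2,
                                      D276G = 2.0, H396R = 1.5),
                        panel, "2024-03-04T05:06:07Z")
  txt <- render_report(rec, "text")
  for (m in panel$known_mutations) expect_match(txt, m$label, fixed = TRUE)
  expect_match(txt, "T315I\\s+clinically_reportable\\s+45.0")
  expect_identical(sum(gregexpr("negative", txt)[[1]] > 0), 11L)
  expect_identical(render_report(rec, "text"), txt)   # byte identical
  html <- render_report(rec, "html")
  expect_match(html, "^<!DOCTYPE html>")
  expect_match(html, "T315I", fixed = TRUE)
})

test_that("QC-failed records carry a banner and assert nothing", {
  rec <- structure(list(sample_id = "bad", run_timestamp = "t",
                        status = "qc_failed",
                        qc = list(passed = FALSE, min_observed_coverage = 12L,
                                  failing_positions = 1:700,
                                  threshold_used = 100L),
                        known_results = NULL, de_novo = NULL, clones = NULL,
                        pipeline_version = "0.0.0", panel_name = "p",
                        panel_hash = "h"),
                   class = "sample_record")
  txt <- render_report(rec, "text")
  expect_match(txt, "QUALITY CONTROL FAILED")
  expect_no_match(txt, "negative\\b")
  expect_no_match(txt, "T315I")
})
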