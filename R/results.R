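#' Append a sample record to the results store
#'
#' The store is an append-only JSON-Lines file: one analysis record per
#' line, never overwritten. Re-analysis of a sample appends a new record.
#' Appending a record identical to one already stored succeeds (with a new
#' id) but raises a warning.
#'
#' @param record A `sample_record` (from [run_sample()]).
#' @param store_path Path to the store file (created on first use).
#' @return The stored record id, invisibly.
#' @export
store_result <- function(record, store_path) {
  stopifnot(inherits(record, "sample_record"))
  existing <- if (file.exists(store_path)) readLines(store_path) else character()
  payload <- unclass(record)
  payload$record_id <- NULL
  body <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                        digits = NA, null = "null",
                                        na = "null"))
  stripped <- vapply(existing, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    x$record_id <- NULL
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, "", USE.NAMES = FALSE)
  if (body %in% stripped)
    warning("an identical record for sample '", record$sample_id,
            "' is already stored; appending anyway", call. = FALSE)
  id <- sprintf("r%06d", length(existing) + 1L)
  payload$record_id <- id
  line <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                        digits = NA, null = "null",
                                        na = "null"))
  con <- tryCatch(file(store_path, open = "a"),
                  error = function(e)
                    stop("cannot open results store '", store_path, "': ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(line, con)
  invisible(id)
}

#' Read every record from a results store
#'
#' @param store_path JSON-Lines store file.
#' @return List of `sample_record` objects.
#' @export
read_store <- function(store_path) {
  if (!file.exists(store_path)) return(list())
  lines <- readLines(store_path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    for (fld in c("known_results", "de_novo", "isoform_votes"))
      if (!is.null(x[[fld]]))
        x[[fld]] <- do.call(rbind, lapply(x[[fld]], function(row)
          as.data.frame(lapply(row, function(v) if (is.null(v)) NA else v),
                        stringsAsFactors = FALSE)))
    if (!is.null(x$clones) && !is.null(x$clones$clones))
      x$clones$clones <- do.call(rbind, lapply(x$clones$clones, function(row)
        as.data.frame(row, stringsAsFactors = FALSE)))
    structure(x, class = "sample_record")
  })
}

#' Fetch one record by id
#'
#' @param store_path Store file.
#' @param record_id Id returned by [store_result()].
#' @return A `sample_record`, or an error when absent.
#' @export
fetch_result <- function(store_path, record_id) {
  recs <- read_store(store_path)
  ids <- vapply(recs, `[[`, "", "record_id")
  hit <- which(ids == record_id)
  if (length(hit) == 0)
    stop("no record '", record_id, "' in ", store_path, call. = FALSE)
  recs[[hit[1]]]
}

#' Search the results store
#'
#' Filters are conjunctive; omitted filters match everything. The mutation
#' filter matches records whose catalogued-mutation results contain the
#' label at `min_status` or stronger. Output order is deterministic:
#' sample id, then run timestamp.
#'
#' @param store_path Store file (or a list of records from [read_store()]).
#' @param sample_id Optional sample id filter.
#' @param mutation Optional mutation label filter (e.g. `"T315I"`).
#' @param min_status `"positive"` (default) or `"clinically_reportable"`:
#'   weakest status the mutation filter accepts.
#' @param status Optional record status filter (`"ok"`, `"qc_failed"`).
#' @param from,to Optional run-timestamp range (inclusive, as
#'   `"YYYY-MM-DD"` strings or anything comparable to the stored
#'   timestamps).
#' @return Data frame of matching record summaries: `record_id`,
#'   `sample_id`, `run_timestamp`, `status`, `isoform_id`, `mutations`
#'   (comma-joined positive or stronger labels with VAF percentages).
#' @export
query_samples <- function(store_path, sample_id = NULL, mutation = NULL,
                          min_status = c("positive", "clinically_reportable"),
                          status = NULL, from = NULL, to = NULL) {
  min_status <- match.arg(min_status)
  accepted <- if (min_status == "positive")
    c("positive", "clinically_reportable") else "clinically_reportable"
  recs <- if (is.character(store_path)) read_store(store_path) else store_path
  rows <- lapply(recs, function(r) {
    kr <- r$known_results
    pos <- if (!is.null(kr) && nrow(kr))
      kr[kr$status %in% accepted, , drop = FALSE]
    else kr
    data.frame(
      record_id = r$record_id %||% NA_character_,
      sample_id = as.character(r$sample_id),
      run_timestamp = r$run_timestamp,
      status = r$status,
      isoform_id = r$isoform_id %||% NA_character_,
      mutations = if (!is.null(pos) && nrow(pos))
        paste(sprintf("%s (%.1f%%)", pos$label, 100 * pos$vaf),
              collapse = ", ")
      else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(record_id = character(), sample_id = character(),
                      run_timestamp = character(), status = character(),
                      isoform_id = character(), mutations = character()))
  keep <- rep(TRUE, nrow(out))
  if (!is.null(sample_id)) keep <- keep & out$sample_id %in% as.character(sample_id)
  if (!is.null(status)) keep <- keep & out$status %in% status
  if (!is.null(from)) keep <- keep & out$run_timestamp >= from
  if (!is.null(to)) keep <- keep & out$run_timestamp <= to
  if (!is.null(mutation)) {
    hit <- vapply(recs, function(r) {
      kr <- r$known_results
      !is.null(kr) && nrow(kr) > 0 &&
        any(kr$label == mutation & kr$status %in% accepted)
    }, TRUE)
    keep <- keep & hit
  }
  out <- out[keep, , drop = FALSE]
  num <- suppressWarnings(as.numeric(out$sample_id))
  ord <- if (!anyNA(num)) order(num, out$run_timestamp)
         else order(out$sample_id, out$run_timestamp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a clinician-facing sample report
#'
#' The report lists EVERY catalogued mutation with its status — negatives
#' are asserted explicitly, which is the point of the coverage QC — with
#' VAFs as percentages to one decimal, the QC summary, the clone table when
#' phasing ran, and the pipeline version and panel hash for traceability.
#' A record whose analysis was aborted at QC carries a failure banner and
#' makes no negative claims. Rendering is deterministic: the same record
#' always produces byte-identical output.
#'
#' @param record A `sample_record`.
#' @param format `"text"` or `"html"`.
#' @return A single character string.
#' @export
render_report <- function(record, format = c("text", "html")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "sample_record"))
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Mutation report — sample %s", record$sample_id)
  add("run: %s | pipeline %s | panel %s (%s)",
      record$run_timestamp, record$pipeline_version,
      record$panel_name %||% "?", substr(record$panel_hash %||% "", 1, 12))
  add("isoform: %s", record$isoform_id %||% "not assigned")
  if (identical(record$status, "qc_failed")) {
    qc <- record$qc
    add("")
    add("*** QUALITY CONTROL FAILED — ANALYSIS ABORTED ***")
    add("minimum observed coverage %d is below the required %d (%d positions)",
        qc$min_observed_coverage, qc$threshold_used,
        length(qc$failing_positions))
    add("No mutation results are reported for this sample: absence of")
    add("evidence at an under-covered site is not evidence of absence.")
  } else {
    qc <- record$qc
    add("QC: passed (min coverage %d, threshold %d)",
        qc$min_observed_coverage, qc$threshold_used)
    add("")
    add("%-8s %-12s %10s %10s  %s", "label", "status", "VAF(%)",
        "alt reads", "codon coverage")
    kr <- record$known_results
    for (i in seq_len(nrow(kr))) {
      add("%-8s %-12s %10.1f %10d  %d", kr$label[i], kr$status[i],
          100 * kr$vaf[i], kr$supporting_reads[i], kr$codon_coverage[i])
    }
    dn <- record$de_novo
    extra <- if (!is.null(dn) && nrow(dn)) dn[!dn$known, , drop = FALSE]
             else NULL
    if (!is.null(extra) && nrow(extra)) {
      add("")
      add("de novo substitutions (not in the catalogue):")
      for (i in seq_len(nrow(extra)))
        add("  pos %d %s>%s  VAF %.1f%%  (%s)", extra$position[i],
            extra$ref_base[i], extra$alt_base[i], 100 * extra$vaf[i],
            ifelse(is.na(extra$aa_label[i]), "non-coding/synonymous",
                   extra$aa_label[i]))
    }
    if (!is.null(record$clones)) {
      ct <- record$clones
      add("")
      add("clonal distribution over {%s} (%d informative reads):",
          paste(ct$sites, collapse = ", "), ct$n_informative)
      cl <- ct$clones
      for (i in seq_len(nrow(cl))) {
        lab <- if (cl$mutations[i] == "") "wild-type" else cl$mutations[i]
        add("  %-28s %6d reads  %5.1f%%  %s", lab, cl$reads[i],
            100 * cl$fraction[i], strrep("#", round(40 * cl$fraction[i])))
      }
    }
  }
  txt <- paste(ln, collapse = "\n")
  if (format == "text") return(txt)
  esc <- gsub("<", "&lt;", gsub("&", "&amp;", txt))
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
         "<title>Sample ", record$sample_id, "</title></head>\n",
         "<body><pre>\n", esc, "\n</pre></body></html>\n")
}
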