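# Post-calling quality filters for somatic variant records.
#
# Substitutions: ASMD >= 140 (median alignment score of supporting reads)
# and CLPM = 0 (clipped-read metric). Note the source rule pairs the
# parenthetical threshold "CLPM = 0" with looser prose ("fewer than half of
# the reads were clipped"); the parenthetical is the operational rule and is
# what this module enforces.
# Indels: quality score >= 300 (only calls below 300 are removed).
# Rearrangements: an assembly score, or else read support >= 4 in tumour /
# >= 25 in normal samples.

.need_field <- function(record, field, class) {
  if (!field %in% names(record) || is.na(record[[field]])) {
    stop("missing field '", field, "' required to filter a ", class,
         " record", call. = FALSE)
  }
  record[[field]]
}

#' Quality-filter a substitution call
#'
#' Passes iff `asmd >= 140` and `clpm == 0`.
#'
#' @param record A one-row data.frame or named list with fields `asmd` and
#'   `clpm`.
#' @return list(pass = logical, failed = character vector of rule names).
#' @export
filter_substitution <- function(record) {
  asmd <- .need_field(record, "asmd", "substitution")
  clpm <- .need_field(record, "clpm", "substitution")
  failed <- character(0)
  if (asmd < 140) failed <- c(failed, "asmd")
  if (clpm != 0) failed <- c(failed, "clpm")
  list(pass = length(failed) == 0L, failed = failed)
}

#' Quality-filter an indel call
#'
#' Passes iff `quality >= 300`.
#'
#' @param record A one-row data.frame or named list with field `quality`.
#' @return list(pass, failed).
#' @export
filter_indel <- function(record) {
  q <- .need_field(record, "quality", "indel")
  failed <- if (q < 300) "quality" else character(0)
  list(pass = length(failed) == 0L, failed = failed)
}

#' Quality-filter a rearrangement call
#'
#' Passes iff an assembly score is present, or read support meets the
#' sample-type minimum (4 in tumour, 25 in normal samples). Presence of an
#' assembly score suffices on its own; no minimum value is imposed.
#'
#' @param record A one-row data.frame or named list with fields
#'   `sample_type`, `supporting_reads` and optionally `assembly_score`.
#' @return list(pass, failed).
#' @export
filter_rearrangement <- function(record) {
  st <- record[["sample_type"]]
  if (is.null(st) || is.na(st)) {
    stop("missing field 'sample_type' required to filter a rearrangement record",
         call. = FALSE)
  }
  if (!st %in% c("tumour", "normal")) {
    stop("sample_type must be 'tumour' or 'normal', got '", st, "'", call. = FALSE)
  }
  has_assembly <- !is.null(record[["assembly_score"]]) &&
    !is.na(record[["assembly_score"]])
  reads <- record[["supporting_reads"]]
  if (is.null(reads) || is.na(reads)) reads <- 0L
  min_reads <- if (st == "tumour") 4L else 25L
  failed <- if (has_assembly || reads >= min_reads) character(0) else "support"
  list(pass = length(failed) == 0L, failed = failed)
}

#' Apply all quality filters to a variant record table
#'
#' Dispatches each record by its `class` column to the appropriate rule set
#' and assembles a per-record and per-rule report. Order-invariant and
#' idempotent: filtering the passing subset again changes nothing.
#'
#' @param records data.frame of variant records (columns `id`, `class` and
#'   the class-appropriate quality fields).
#' @return A `filter_report`: list with `records` (input plus `pass` and
#'   `failed_rules` columns), `summary` (rule -> failure count) and
#'   `n_pass` / `n_fail`.
#' @export
apply_filters <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("apply_filters: records must be a non-empty data.frame", call. = FALSE)
  }
  if (!"class" %in% names(records)) stop("records need a 'class' column", call. = FALSE)
  verdicts <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    switch(as.character(rec$class),
      substitution = filter_substitution(rec),
      indel = filter_indel(rec),
      rearrangement = filter_rearrangement(rec),
      stop("unknown variant class: ", rec$class, call. = FALSE)
    )
  })
  pass <- vapply(verdicts, `[[`, logical(1), "pass")
  failed <- lapply(verdicts, `[[`, "failed")
  all_rules <- c("asmd", "clpm", "quality", "support")
  summary <- vapply(all_rules, function(r) {
    sum(vapply(failed, function(f) r %in% f, logical(1)))
  }, integer(1))
  out <- records
  out$pass <- pass
  out$failed_rules <- vapply(failed, function(f) paste(f, collapse = ";"),
                             character(1))
  structure(list(records = out, summary = summary,
                 n_pass = sum(pass), n_fail = sum(!pass)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_pass, "pass,", x$n_fail, "fail of",
      nrow(x$records), "records\n")
  for (r in names(x$summary)) {
    if (x$summary[[r]] > 0) cat(sprintf("  rule %-8s failed %d record(s)\n",
                                        r, x$summary[[r]]))
  }
  invisible(x)
}
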