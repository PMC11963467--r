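#' Construct a coverage row
#'
#' One line of the coverage statistics: how many concepts a scope contains,
#' how many are mapped to at least one template element, and how many of
#' those map to structured (non-narrative) content. Percentages are integer
#' percents of the concept total under half-up rounding.
#'
#' @param label row label (use case or concept group)
#' @param concepts,mapped,structured non-negative counts with
#'   `structured <= mapped <= concepts`
#' @return list of class `coverage_row` with fields `label`, `concepts`,
#'   `mapped`, `mapped_pct`, `structured`, `structured_pct`
#' @export
coverage_row <- function(label, concepts, mapped, structured) {
  concepts <- as.integer(concepts)
  mapped <- as.integer(mapped)
  structured <- as.integer(structured)
  if (structured > mapped || mapped > concepts || structured < 0L) {
    abort(sprintf(
      "invalid coverage row '%s': need 0 <= structured (%d) <= mapped (%d) <= concepts (%d)",
      label, structured, mapped, concepts))
  }
  structure(list(label = chr1(label, "label"), concepts = concepts,
                 mapped = mapped, mapped_pct = pct_of(mapped, concepts),
                 structured = structured,
                 structured_pct = pct_of(structured, concepts)),
            class = "coverage_row")
}

#' Construct a coverage report
#'
#' @param use_case_rows named list (by use case) of lists with fields
#'   `row` (a [coverage_row()]) and `groups` (list of [coverage_row()]s)
#' @param overall optional overall [coverage_row()]; recomputed from the
#'   use-case rows when omitted
#' @return object of class `coverage_report`
#' @export
coverage_report <- function(use_case_rows, overall = NULL) {
  if (is.null(overall)) {
    tot <- function(f) sum(vapply(use_case_rows,
                                  function(u) u$row[[f]], integer(1)))
    overall <- coverage_row("Overall", tot("concepts"), tot("mapped"),
                            tot("structured"))
  }
  for (u in use_case_rows) {
    gsum <- function(f) sum(vapply(u$groups, function(g) g[[f]], integer(1)))
    if (length(u$groups) &&
        (gsum("concepts") != u$row$concepts || gsum("mapped") != u$row$mapped ||
         gsum("structured") != u$row$structured)) {
      abort(sprintf("group rows of '%s' do not add up to the use-case row",
                    u$row$label))
    }
  }
  structure(list(use_cases = use_case_rows, overall = overall),
            class = "coverage_report")
}

# internal: row -> plain list in fixed (sorted) key order
row_as_list <- function(r, with_groups = NULL) {
  base <- list(concepts = r$concepts)
  if (!is.null(with_groups)) base$groups <- with_groups
  c(base, list(label = r$label, mapped = r$mapped, mapped_pct = r$mapped_pct,
               structured = r$structured, structured_pct = r$structured_pct))
}

#' Convert a coverage report to a plain list
#'
#' The canonical list form matches the YAML schema shipped in
#' `inst/schema/coverage-report.schema.json`: an `overall` block and a
#' `use_cases` mapping whose entries carry their group rows; keys appear in
#' sorted order.
#'
#' @param report a [coverage_report()]
#' @return a nested list of plain vectors
#' @export
report_as_list <- function(report) {
  stopifnot(inherits(report, "coverage_report"))
  ucs <- report$use_cases
  if (length(ucs)) ucs <- ucs[order(names(ucs), method = "radix")]
  list(
    overall = row_as_list(report$overall),
    use_cases = map(ucs, function(u) {
      groups <- sort_by_key(u$groups, function(g) g$label)
      row_as_list(u$row, with_groups = map(groups, row_as_list))
    })
  )
}

#' Write the YAML coverage report
#'
#' Deterministic: identical reports yield byte-identical YAML.
#'
#' @param report a [coverage_report()]
#' @param path optional file path; when given the text is also written there
#' @return YAML text, invisibly when `path` is given
#' @export
write_report_yaml <- function(report, path = NULL) {
  txt <- yaml::as.yaml(report_as_list(report), indent = 2,
                       precision = 12)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' @export
print.coverage_report <- function(x, ...) {
  fmt <- function(r) sprintf("%-28s %4d  %4d (%d%%)  %4d (%d%%)",
                             r$label, r$concepts, r$mapped, r$mapped_pct,
                             r$structured, r$structured_pct)
  cat("<coverage_report>\n")
  cat(sprintf("%-28s %4s  %-11s %-11s\n", "", "n", "mapped", "structured"))
  for (u in x$use_cases) cat(fmt(u$row), "\n")
  cat(fmt(x$overall), "\n")
  invisible(x)
}
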