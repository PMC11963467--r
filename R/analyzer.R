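#' @name analyzer
#' @title Coverage analysis of concept-to-template mappings
#'
#' @description
#' The analyzer combines a resolved concept repository, the template
#' associations (automatic and manual), and the template repositories into
#' coverage statistics: per use case, per top-level concept group, and
#' overall. A concept is `mapped_structured` as soon as any of its
#' associations touches a structured (non-narrative) element — structured
#' targets take precedence over free-text targets — `mapped_free_text` when
#' all its targets are narrative, and `unmapped` without associations.
#' Concepts shared between use cases are counted once per use case, so the
#' overall totals are the sums of the use-case rows.
NULL

#' Classify a template element as structured or free text
#'
#' @param el a [template_element()]
#' @return `"structured"` for coded/quantity/datetime/boolean content,
#'   `"free_text"` for narrative text
#' @export
classify_element <- function(el) {
  if (el$content_kind == "narrative_text") "free_text" else "structured"
}

#' Classify a concept's mapping status
#'
#' @param concept_id concept identifier
#' @param associations association documents/lists (see
#'   [analyze_coverage()]); only associations of this concept are considered
#' @param template_repos a [template_repository()] or list of them
#' @return `"unmapped"`, `"mapped_free_text"`, or `"mapped_structured"`
#' @export
classify_concept <- function(concept_id, associations, template_repos) {
  assocs <- keep(collect_associations(associations),
                 function(a) a$concept_id == concept_id)
  statuses <- character()
  for (a in assocs) {
    t <- find_template(template_repos, a$template_id, a$effective_date)
    if (is.null(t)) {
      abort(sprintf(
        "association of concept '%s' targets missing template '%s' (%s)",
        concept_id, a$template_id, a$effective_date))
    }
    if (!t$normative) {
      warn(sprintf(
        "association of concept '%s' targets non-normative template '%s'; ignored",
        concept_id, a$template_id))
      next
    }
    els <- setNames(t$elements,
                    vapply(t$elements, function(e) e$element_id, character(1)))
    for (eid in a$element_ids) {
      el <- els[[eid]]
      if (is.null(el)) {
        abort(sprintf(
          "association of concept '%s' targets missing element '%s' of template '%s'",
          concept_id, eid, a$template_id))
      }
      statuses <- c(statuses, classify_element(el))
    }
  }
  if (length(statuses) == 0L) return("unmapped")
  if (any(statuses == "structured")) "mapped_structured" else "mapped_free_text"
}

#' Compute the coverage report
#'
#' @param repo a [concept_repository()]; inheritance is resolved internally
#' @param associations an [association_document()], a list of them, or a
#'   (possibly nested) list of [template_association()]s — automatic and
#'   manual mappings are simply pooled
#' @param template_repos a [template_repository()] or list of them
#' @return a [coverage_report()] with one row per use-case dataset (basic
#'   datasets are counted through inheritance, not as rows), nested
#'   per-group rows keyed by the first element of each concept's group path,
#'   and an overall row summing the use-case rows
#' @export
analyze_coverage <- function(repo, associations, template_repos) {
  repo <- resolve_inheritance(repo)
  assocs <- collect_associations(associations)
  cache <- new.env(parent = emptyenv())
  status_of <- function(concept_id) {
    if (is.null(cache[[concept_id]])) {
      cache[[concept_id]] <- classify_concept(concept_id, assocs,
                                              template_repos)
    }
    cache[[concept_id]]
  }

  uc_order <- c("feasibility", "recruitment", "execution")
  datasets <- keep(repo$datasets, function(ds) ds$use_case != "basic")
  datasets <- datasets[order(match(
    vapply(datasets, function(ds) ds$use_case, character(1)), uc_order),
    method = "radix")]

  use_case_rows <- list()
  for (ds in datasets) {
    st <- vapply(ds$concepts, function(co) status_of(co$id), character(1))
    grp <- vapply(ds$concepts, function(co) co$group_path[[1]], character(1))
    groups <- lapply(sort(unique(grp), method = "radix"), function(g) {
      sel <- grp == g
      coverage_row(g, sum(sel), sum(sel & st != "unmapped"),
                   sum(sel & st == "mapped_structured"))
    })
    row <- coverage_row(ds$use_case, length(st), sum(st != "unmapped"),
                        sum(st == "mapped_structured"))
    use_case_rows[[ds$use_case]] <- list(row = row, groups = groups)
  }
  coverage_report(use_case_rows)
}
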