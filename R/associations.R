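#' Construct a template association
#'
#' A template association is the formal link between a trial concept and the
#' CDA template element(s) that can hold its data. A mapping onto a generic
#' template (one specialized by the value of its own `code` element, such as
#' a generic lab observation) spans two elements — the code element and the
#' value element — and carries the specializing code as a qualifier.
#'
#' @param concept_id id of the mapped concept
#' @param template_id,effective_date identify the target template version
#' @param element_ids character vector of one or two element ids
#' @param qualifier optional `list(system =, code =, display =)` qualifier
#'   code for generic-template mappings
#' @param provenance `"automatic"` (code-based matching) or `"manual"`
#' @return object of class `template_association`
#' @export
template_association <- function(concept_id, template_id, effective_date,
                                 element_ids, qualifier = NULL,
                                 provenance = c("manual", "automatic")) {
  provenance <- match.arg(provenance)
  element_ids <- vapply(element_ids, chr1, character(1), what = "element_ids")
  if (length(element_ids) < 1L || length(element_ids) > 2L ||
      anyDuplicated(element_ids)) {
    abort("`element_ids` must hold one or two distinct element ids")
  }
  if (!is.null(qualifier)) {
    qualifier <- list(system = canonical_system(chr1(qualifier$system, "system")),
                      code = chr1(qualifier$code, "code"),
                      display = as.character(qualifier$display %||% NA_character_))
  }
  structure(list(concept_id = chr1(concept_id, "concept_id"),
                 template_id = chr1(template_id, "template_id"),
                 effective_date = chr1(effective_date, "effective_date"),
                 element_ids = sort(unname(element_ids), method = "radix"),
                 qualifier = qualifier, provenance = provenance),
            class = "template_association")
}

# internal: canonical identity key of an association
association_key <- function(a) {
  q <- if (is.null(a$qualifier)) "" else {
    paste(a$qualifier$system, a$qualifier$code, sep = SEP)
  }
  paste(a$concept_id, a$template_id, a$effective_date,
        paste(a$element_ids, collapse = ","), q, a$provenance, sep = SEP)
}

#' Construct an association document
#'
#' A project file holding a set of [template_association()] records.
#' Duplicate identical associations are collapsed with a warning.
#'
#' @param project_id project identifier
#' @param associations list of [template_association()] objects
#' @return object of class `association_document`
#' @export
association_document <- function(project_id, associations = list()) {
  keys <- vapply(associations, association_key, character(1))
  if (anyDuplicated(keys)) {
    warn(sprintf("%d duplicate association(s) removed",
                 sum(duplicated(keys))))
    associations <- associations[!duplicated(keys)]
  }
  structure(list(project_id = chr1(project_id, "project_id"),
                 associations = sort_by_key(associations, association_key)),
            class = "association_document")
}

# internal: pool associations from documents and/or bare lists
collect_associations <- function(assocs) {
  if (inherits(assocs, "association_document")) return(assocs$associations)
  if (inherits(assocs, "template_association")) return(list(assocs))
  out <- list()
  for (x in assocs) out <- c(out, collect_associations(x))
  out
}
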