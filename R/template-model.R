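#' @name template_model
#' @title CDA template repository model
#'
#' @description
#' The content of an HL7 CDA based shared EHR system is constrained by
#' templates, distributed in building-block repositories (BBRs). For coverage
#' analysis a template is reduced to its identified elements, each with a
#' content kind (`coded`, `quantity`, `datetime`, `boolean`,
#' `narrative_text`) and an optional terminology binding: a fixed code or a
#' value-set reference. Value sets are versioned by effective date; a binding
#' names the value set only, and matching considers every version present in
#' the repository. Templates referenced by a document type of normative
#' status are the ones actually in productive use; only those participate in
#' code matching.
NULL

template_content_kinds <- c("coded", "quantity", "datetime", "boolean",
                            "narrative_text")

#' Construct a template element
#'
#' @param element_id identifier, unique within its template
#' @param path slash-separated element path with `hl7:` prefixes,
#'   e.g. `"hl7:code"` or `"hl7:value"`
#' @param content_kind one of `coded`, `quantity`, `datetime`, `boolean`,
#'   `narrative_text`
#' @param binding `list(kind = "none")`,
#'   `list(kind = "fixed", system =, code =, display =)`, or
#'   `list(kind = "valueset", valueset_id =)`; narrative elements must be
#'   unbound and fixed/value-set bindings are only allowed on coded elements
#' @return object of class `template_element`
#' @export
template_element <- function(element_id, path, content_kind,
                             binding = list(kind = "none")) {
  element_id <- chr1(element_id, "element_id")
  path <- chr1(path, "path")
  content_kind <- match.arg(content_kind, template_content_kinds)
  if (!is.list(binding) || is.null(binding$kind) ||
      !binding$kind %in% c("none", "fixed", "valueset")) {
    abort(sprintf("element '%s': invalid binding", element_id))
  }
  if (binding$kind != "none" && content_kind != "coded") {
    abort(sprintf(
      "element '%s': %s binding requires content kind 'coded' (got '%s')",
      element_id, binding$kind, content_kind))
  }
  if (binding$kind == "fixed") {
    binding <- list(kind = "fixed",
                    system = canonical_system(chr1(binding$system, "system")),
                    code = chr1(binding$code, "code"),
                    display = as.character(binding$display %||% NA_character_))
  } else if (binding$kind == "valueset") {
    binding <- list(kind = "valueset",
                    valueset_id = chr1(binding$valueset_id, "valueset_id"))
  } else {
    binding <- list(kind = "none")
  }
  structure(list(element_id = element_id, path = path,
                 content_kind = content_kind, binding = binding),
            class = "template_element")
}

#' Construct a CDA template
#'
#' @param template_id OID-like identifier
#' @param effective_date ISO-8601 date-time string; acts as the version key
#'   and is compared lexicographically
#' @param name template label
#' @param elements non-empty list of [template_element()] objects
#' @param normative whether the template is referenced by a normative
#'   document type (i.e. is live in the EHR system)
#' @return object of class `cda_template`
#' @export
cda_template <- function(template_id, effective_date, name = template_id,
                         elements, normative = TRUE) {
  template_id <- chr1(template_id, "template_id")
  effective_date <- chr1(effective_date, "effective_date")
  if (length(elements) == 0L) {
    abort(sprintf("template '%s' needs at least one element", template_id))
  }
  eids <- vapply(elements, function(el) el$element_id, character(1))
  if (anyDuplicated(eids)) {
    abort(sprintf("duplicate element id(s) in template '%s'", template_id))
  }
  structure(list(template_id = template_id, effective_date = effective_date,
                 name = chr1(name, "name"), elements = elements,
                 normative = isTRUE(normative)),
            class = "cda_template")
}

#' Construct a value set
#'
#' @param valueset_id identifier
#' @param effective_date ISO-8601 version key
#' @param codes non-empty code table from [code_tbl()]
#' @return object of class `value_set`
#' @export
value_set <- function(valueset_id, effective_date, codes) {
  codes <- code_tbl(codes$system, codes$code, codes$display)
  if (nrow(codes) == 0L) {
    abort(sprintf("value set '%s' must contain at least one code", valueset_id))
  }
  structure(list(valueset_id = chr1(valueset_id, "valueset_id"),
                 effective_date = chr1(effective_date, "effective_date"),
                 codes = codes),
            class = "value_set")
}

#' Construct a template repository (BBR)
#'
#' @param repository_id identifier of the building-block repository
#' @param templates list of [cda_template()] objects; (id, effective date)
#'   pairs must be unique
#' @param value_sets list of [value_set()] objects; (id, effective date)
#'   pairs must be unique
#' @return object of class `template_repository`
#' @export
template_repository <- function(repository_id, templates = list(),
                                value_sets = list()) {
  tkeys <- vapply(templates, function(t) {
    paste(t$template_id, t$effective_date, sep = SEP)
  }, character(1))
  if (anyDuplicated(tkeys)) {
    abort("duplicate (template_id, effective_date) in repository")
  }
  vkeys <- vapply(value_sets, function(v) {
    paste(v$valueset_id, v$effective_date, sep = SEP)
  }, character(1))
  if (anyDuplicated(vkeys)) {
    abort("duplicate (valueset_id, effective_date) in repository")
  }
  vs_ids <- unique(vapply(value_sets, function(v) v$valueset_id, character(1)))
  for (t in templates) {
    for (el in t$elements) {
      if (el$binding$kind == "valueset" &&
          !el$binding$valueset_id %in% vs_ids) {
        abort(sprintf(
          "template '%s' element '%s' binds missing value set '%s'",
          t$template_id, el$element_id, el$binding$valueset_id))
      }
    }
  }
  structure(list(repository_id = chr1(repository_id, "repository_id"),
                 templates = sort_by_key(templates, function(t) {
                   paste(t$template_id, t$effective_date, sep = SEP)
                 }),
                 value_sets = sort_by_key(value_sets, function(v) {
                   paste(v$valueset_id, v$effective_date, sep = SEP)
                 })),
            class = "template_repository")
}

# internal: find a template by id (+ optional effective date; latest if NA)
find_template <- function(repos, template_id, effective_date = NA) {
  if (inherits(repos, "template_repository")) repos <- list(repos)
  hits <- list()
  for (repo in repos) {
    for (t in repo$templates) {
      if (t$template_id != template_id) next
      if (!is.na(effective_date) && t$effective_date != effective_date) next
      hits[[length(hits) + 1L]] <- t
    }
  }
  if (length(hits) == 0L) return(NULL)
  dates <- vapply(hits, function(t) t$effective_date, character(1))
  hits[[order(dates, method = "radix", decreasing = TRUE)[1]]]
}

# internal: all versions of a value set within one repository
find_value_sets <- function(repo, valueset_id) {
  keep(repo$value_sets, function(v) v$valueset_id == valueset_id)
}

#' @export
print.template_repository <- function(x, ...) {
  cat(sprintf("<template_repository> '%s': %d template(s), %d value set(s)\n",
              x$repository_id, length(x$templates), length(x$value_sets)))
  invisible(x)
}
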