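#' @name matcher
#' @title Exact code-based concept-to-template matching
#'
#' @description
#' The matcher scans the code bindings of the normative CDA templates for
#' codes that also occur in a concept's expanded code set. Matching is exact
#' on the canonical (system, code) pair; there is no lexical matching of
#' display names. Raw matches ("candidates") are then consolidated — value
#' set versions deduplicated, codes hitting the same value set grouped — and
#' after manual validation the accepted candidates are converted into formal
#' template associations. Mappings onto generic templates (a coded element
#' with a value-set binding plus a sibling value element) become paired
#' associations carrying the matched code as a qualifier.
NULL

#' Build a code index over a template repository
#'
#' Indexes every fixed code binding and every code of every version of every
#' bound value set of the normative templates. Lookups over the index agree
#' with a linear scan of the repository.
#'
#' @param repo a [template_repository()] or list of them
#' @return tibble of class `code_index` with one row per code occurrence:
#'   `system`, `code`, `template_id`, `template_date`, `element_id`, `via`
#'   (`"fixed"` or `"valueset"`), `valueset_id`, `valueset_date`
#' @export
index_codes <- function(repo) {
  repos <- if (inherits(repo, "template_repository")) list(repo) else repo
  rows <- list()
  for (rp in repos) {
    for (t in rp$templates) {
      if (!t$normative) next
      for (el in t$elements) {
        b <- el$binding
        if (b$kind == "fixed") {
          rows[[length(rows) + 1L]] <- tibble(
            system = b$system, code = b$code, template_id = t$template_id,
            template_date = t$effective_date, element_id = el$element_id,
            via = "fixed", valueset_id = NA_character_,
            valueset_date = NA_character_)
        } else if (b$kind == "valueset") {
          for (v in find_value_sets(rp, b$valueset_id)) {
            rows[[length(rows) + 1L]] <- tibble(
              system = v$codes$system, code = v$codes$code,
              template_id = t$template_id, template_date = t$effective_date,
              element_id = el$element_id, via = "valueset",
              valueset_id = v$valueset_id, valueset_date = v$effective_date)
          }
        }
      }
    }
  }
  idx <- if (length(rows)) bind_rows(rows) else {
    tibble(system = character(), code = character(),
           template_id = character(), template_date = character(),
           element_id = character(), via = character(),
           valueset_id = character(), valueset_date = character())
  }
  idx <- distinct(idx)
  idx <- idx[order(idx$system, idx$code, idx$template_id, idx$template_date,
                   idx$element_id, idx$valueset_id, idx$valueset_date,
                   method = "radix"), , drop = FALSE]
  class(idx) <- c("code_index", class(idx))
  idx
}

#' Match expanded concept codes against a code index
#'
#' @param expanded list of [expand_codes()] results
#' @param index a [index_codes()] index
#' @return list of `candidate_match` objects, one per concept with at least
#'   one hit, ordered by concept id; each has fields `concept_id`,
#'   `occurrences` (rows of the index that matched) and
#'   `status = "pending"`. Concepts without hits are absent.
#' @export
match_concepts <- function(expanded, index) {
  if (inherits(expanded, "expanded_code_set")) expanded <- list(expanded)
  out <- list()
  for (ex in expanded) {
    if (nrow(ex$codes) == 0L) next
    hits <- index[code_keys(index) %in% code_keys(ex$codes), , drop = FALSE]
    if (nrow(hits) == 0L) next
    out[[length(out) + 1L]] <- structure(
      list(concept_id = ex$concept_id,
           occurrences = as_tibble(hits), status = "pending",
           reason = NULL),
      class = "candidate_match")
  }
  sort_by_key(out, function(cm) cm$concept_id)
}

#' Consolidate candidate matches
#'
#' Two cleanup steps mirroring the manual validation workflow: occurrences
#' that differ only in the value-set effective date collapse onto the latest
#' value-set version, and occurrences of different codes on the same
#' (template, element, value set) merge into one grouped occurrence carrying
#' the full code list. Candidates are neither added nor removed, and the
#' operation is idempotent.
#'
#' @param candidates list of candidates from [match_concepts()]
#' @return candidates whose `occurrences` tibble has one row per
#'   (template, element, binding) with a `codes` list-column of matched
#'   (system, code) tibbles
#' @export
consolidate_candidates <- function(candidates) {
  map(candidates, function(cm) {
    occ <- cm$occurrences
    if ("codes" %in% names(occ)) {
      occ <- tidyr::unnest(select(occ, -dplyr::any_of(c("system", "code"))),
                           "codes")
    }
    # value-set version dedup: keep the lexicographically latest date per
    # (code, template, element, value set)
    vs <- occ$via == "valueset"
    if (any(vs)) {
      vocc <- occ[vs, , drop = FALSE]
      grp <- paste(vocc$system, vocc$code, vocc$template_id,
                   vocc$template_date, vocc$element_id, vocc$valueset_id,
                   sep = SEP)
      latest <- tapply(vocc$valueset_date, grp, max)
      keep_row <- vocc$valueset_date == unname(latest[grp])
      occ <- bind_rows(occ[!vs, , drop = FALSE], vocc[keep_row, , drop = FALSE])
    }
    # group codes hitting the same binding
    key <- paste(occ$template_id, occ$template_date, occ$element_id, occ$via,
                 occ$valueset_id, occ$valueset_date, sep = SEP)
    pieces <- lapply(split(seq_len(nrow(occ)), key), function(ix) {
      sub <- occ[ix, , drop = FALSE]
      codes <- code_tbl(sub$system, sub$code)[, c("system", "code")]
      tibble(template_id = sub$template_id[1],
             template_date = sub$template_date[1],
             element_id = sub$element_id[1], via = sub$via[1],
             valueset_id = sub$valueset_id[1],
             valueset_date = sub$valueset_date[1],
             codes = list(codes))
    })
    merged <- bind_rows(pieces)
    merged <- merged[order(merged$template_id, merged$template_date,
                           merged$element_id, merged$valueset_id,
                           method = "radix"), , drop = FALSE]
    cm$occurrences <- merged
    cm
  })
}

#' Set the validation status of candidate matches
#'
#' Candidates start `pending`; manual validation moves them to `accepted` or
#' `rejected` (with a reason). Transitions away from a decided status are
#' refused.
#'
#' @param candidates list of candidates
#' @param status `"accepted"` or `"rejected"`
#' @param concept_ids ids to update; default all pending candidates
#' @param reason free-text reason, required for rejections
#' @return updated candidate list
#' @export
set_candidate_status <- function(candidates, status = c("accepted", "rejected"),
                                 concept_ids = NULL, reason = NULL) {
  status <- match.arg(status)
  if (status == "rejected" && is.null(reason)) {
    abort("rejecting candidates requires a `reason`")
  }
  map(candidates, function(cm) {
    if (!is.null(concept_ids) && !cm$concept_id %in% concept_ids) return(cm)
    if (cm$status != "pending") {
      abort(sprintf("candidate '%s' already %s; status transitions only from pending",
                    cm$concept_id, cm$status))
    }
    cm$status <- status
    cm$reason <- reason
    cm
  })
}

# internal: does `template` look generic w.r.t. `element_id`? If so return
# the sibling value element id, else NULL.
generic_value_element <- function(template, element_id) {
  el <- NULL
  for (e in template$elements) if (e$element_id == element_id) el <- e
  if (is.null(el) || el$content_kind != "coded" ||
      el$binding$kind != "valueset") {
    return(NULL)
  }
  for (e in template$elements) {
    if (e$element_id != element_id && e$content_kind != "narrative_text" &&
        grepl("(^|[/:])value$", e$path)) {
      return(e$element_id)
    }
  }
  NULL
}

#' Convert accepted candidates into template associations
#'
#' One association is emitted per (concept, template, element); a match on
#' the coded element of a generic template becomes a paired association
#' spanning the code and value elements, with the matched code as qualifier.
#' Rejected candidates contribute nothing; pending candidates are an error
#' (validate first).
#'
#' @param candidates consolidated candidates (consolidation is applied if
#'   needed)
#' @param template_repos a [template_repository()] or list of them
#' @return list of [template_association()]s with provenance `"automatic"`
#' @export
to_associations <- function(candidates, template_repos) {
  pending <- keep(candidates, function(cm) cm$status == "pending")
  if (length(pending)) {
    abort(sprintf("candidate(s) still pending validation: %s",
                  paste(vapply(pending, function(cm) cm$concept_id,
                               character(1)), collapse = ", ")))
  }
  accepted <- keep(candidates, function(cm) cm$status == "accepted")
  accepted <- consolidate_candidates(accepted)
  out <- list()
  for (cm in accepted) {
    occ <- cm$occurrences
    for (i in seq_len(nrow(occ))) {
      t <- find_template(template_repos, occ$template_id[i],
                         occ$template_date[i])
      if (is.null(t)) {
        abort(sprintf(
          "accepted candidate '%s' references missing template '%s' (%s)",
          cm$concept_id, occ$template_id[i], occ$template_date[i]))
      }
      eids <- vapply(t$elements, function(el) el$element_id, character(1))
      if (!occ$element_id[i] %in% eids) {
        abort(sprintf(
          "accepted candidate '%s' references missing element '%s' of template '%s'",
          cm$concept_id, occ$element_id[i], occ$template_id[i]))
      }
      value_el <- generic_value_element(t, occ$element_id[i])
      codes <- occ$codes[[i]]
      if (!is.null(value_el)) {
        q <- list(system = codes$system[1], code = codes$code[1])
        a <- template_association(cm$concept_id, t$template_id,
                                  t$effective_date,
                                  c(occ$element_id[i], value_el),
                                  qualifier = q, provenance = "automatic")
      } else {
        a <- template_association(cm$concept_id, t$template_id,
                                  t$effective_date, occ$element_id[i],
                                  provenance = "automatic")
      }
      out[[length(out) + 1L]] <- a
    }
  }
  keys <- vapply(out, association_key, character(1))
  sort_by_key(out[!duplicated(keys)], association_key)
}

#' Trace matched candidates back to source codes
#'
#' Reports which of a concept's own repository codes led to at least one
#' template hit — the raw "code hit" count before matches are consolidated
#' into per-concept mappings.
#'
#' @param candidates candidates from [match_concepts()] (consolidated or not)
#' @param expanded the [expand_codes()] results the candidates were built from
#' @return tibble with columns `concept_id`, `source_system`, `source_code`,
#'   one row per source code with at least one hit
#' @export
source_code_hits <- function(candidates, expanded) {
  by_id <- setNames(expanded,
                    vapply(expanded, function(e) e$concept_id, character(1)))
  rows <- list()
  for (cm in candidates) {
    ex <- by_id[[cm$concept_id]]
    if (is.null(ex)) next
    occ <- cm$occurrences
    matched <- if ("codes" %in% names(occ)) {
      unique(unlist(lapply(occ$codes, code_keys)))
    } else {
      unique(code_keys(occ))
    }
    tr <- ex$trace
    hit <- paste(tr$system, tr$code, sep = SEP) %in% matched
    if (!any(hit)) next
    sub <- unique(tr[hit, c("source_system", "source_code"), drop = FALSE])
    rows[[length(rows) + 1L]] <- tibble(concept_id = cm$concept_id,
                                        source_system = sub$source_system,
                                        source_code = sub$source_code)
  }
  if (!length(rows)) {
    return(tibble(concept_id = character(), source_system = character(),
                  source_code = character()))
  }
  res <- bind_rows(rows)
  res[order(res$concept_id, res$source_system, res$source_code,
            method = "radix"), , drop = FALSE]
}
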