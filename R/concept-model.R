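#' @name concept_model
#' @title Trial-concept repository model
#'
#' @description
#' The trial-concept repository holds the data elements ("concepts") that are
#' commonly needed for clinical trial conduct, organized into datasets for the
#' use cases feasibility checking, patient identification/recruitment, and
#' trial execution, plus an optional "basic" dataset of elements shared by
#' several use cases. Shared elements are pulled into the use-case datasets by
#' inheritance, so coverage totals count a shared element once per use case.
#'
#' A concept carries a data type from a closed enumeration
#' (`Quantity`, `Code`, `Count`, `Boolean`, `Date`, `Text`, `Identifier`),
#' a set of terminology codes (typically UMLS concept identifiers, sometimes
#' SNOMED CT), a free-text description, and an ordered group path such as
#' `"Laboratory findings"` used for per-group coverage statistics.
NULL

#' Closed enumeration of concept data types
#' @export
concept_data_types <- c("Quantity", "Code", "Count", "Boolean", "Date",
                        "Text", "Identifier")

#' Use-case labels for concept datasets
#' @export
use_cases <- c("feasibility", "recruitment", "execution", "basic")

#' Construct a trial concept
#'
#' @param id stable identifier, unique within its dataset
#' @param name short label
#' @param data_type one of [concept_data_types]
#' @param codes a code table as built by [code_tbl()]
#' @param group_path character vector of group labels, outermost first;
#'   must be non-empty
#' @param description free text (may be empty)
#' @param origin either `"local"` or a list
#'   `list(dataset = <source dataset id>, concept = <source concept id>)`
#'   marking the concept as inherited
#' @return object of class `trial_concept`
#' @export
concept <- function(id, name = id, data_type = "Text",
                    codes = code_tbl(), group_path = "General",
                    description = "", origin = "local") {
  id <- chr1(id, "id")
  inherited <- is.list(origin)
  if (inherited) {
    if (is.null(origin$dataset) || is.null(origin$concept)) {
      abort("inherited origin needs `dataset` and `concept` fields")
    }
  } else if (!identical(origin, "local")) {
    abort("`origin` must be \"local\" or an inheritance record")
  }
  if (!inherited) {
    if (!is.character(data_type) || length(data_type) != 1L ||
        !data_type %in% concept_data_types) {
      abort(sprintf("unknown data type %s for concept '%s'",
                    deparse(data_type), id))
    }
    group_path <- trimws(as.character(group_path))
    if (length(group_path) == 0L || any(!nzchar(group_path))) {
      abort(sprintf("concept '%s' needs a non-empty group path", id))
    }
  }
  structure(
    list(id = id, name = chr1(name, "name"), data_type = data_type,
         codes = code_tbl(codes$system, codes$code, codes$display),
         group_path = group_path,
         description = as.character(description %||% ""),
         origin = origin),
    class = "trial_concept"
  )
}

#' Construct a concept dataset
#'
#' @param id dataset identifier
#' @param name dataset label
#' @param use_case one of [use_cases]
#' @param concepts list of [concept()] objects (locals and inheritance stubs)
#' @return object of class `concept_dataset`
#' @export
concept_dataset <- function(id, name = id, use_case, concepts = list()) {
  id <- chr1(id, "id")
  use_case <- match.arg(use_case, use_cases)
  ids <- vapply(concepts, function(co) co$id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate concept id(s) in dataset '%s': %s", id,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(
    list(id = id, name = chr1(name, "name"), use_case = use_case,
         concepts = sort_by_key(concepts, function(co) co$id)),
    class = "concept_dataset"
  )
}

#' Construct a concept repository
#'
#' @param project_id project identifier
#' @param datasets list of [concept_dataset()] objects
#' @return object of class `concept_repository`
#' @export
concept_repository <- function(project_id, datasets = list()) {
  ids <- vapply(datasets, function(ds) ds$id, character(1))
  if (anyDuplicated(ids)) abort("duplicate dataset ids in repository")
  repo <- structure(
    list(project_id = chr1(project_id, "project_id"),
         datasets = setNames(datasets, ids)),
    class = "concept_repository"
  )
  check_inheritance_refs(repo)
  repo
}

# internal: every inheritance reference must point at an existing concept
check_inheritance_refs <- function(repo) {
  for (ds in repo$datasets) {
    for (co in ds$concepts) {
      if (!is.list(co$origin)) next
      src_ds <- repo$datasets[[co$origin$dataset]]
      if (is.null(src_ds)) {
        abort(sprintf(
          "concept '%s' in dataset '%s' inherits from unknown dataset '%s'",
          co$id, ds$id, co$origin$dataset))
      }
      src_ids <- vapply(src_ds$concepts, function(x) x$id, character(1))
      if (!co$origin$concept %in% src_ids) {
        abort(sprintf(
          "concept '%s' in dataset '%s' inherits from missing concept '%s'",
          co$id, ds$id, co$origin$concept))
      }
    }
  }
  invisible(repo)
}

#' Normalize a source data-type label to the concept data-type enumeration
#'
#' Source repositories describe data elements with generic form-oriented type
#' labels (`Float`, `Integer`, `Text`, `String`, `Date`, `Boolean`). The
#' concept model uses a richer enumeration, and a semantic hint taken from the
#' element's group decides the more specific type:
#'
#' * quantities (lab values, vital signs) recorded as `Float`, `Integer` or
#'   `Text` become `Quantity`;
#' * coded items (gender, procedure codes) recorded as `String`, `Text` or
#'   `Integer` become `Code`;
#' * counts ("number of pregnancies", "years smoked") recorded as `Integer`
#'   or `Float` become `Count`.
#'
#' Without an applicable hint the label maps by identity into the
#' enumeration; `Float` and `Integer` have no identity image and default to
#' `Quantity` and `Count`, `String` folds into `Text`.
#'
#' @param source_type one of `Float`, `Integer`, `Text`, `String`, `Date`,
#'   `Boolean`
#' @param semantic_hint one of `"none"`, `"quantity"`, `"code"`, `"count"`
#' @return a single [concept_data_types] value
#' @examples
#' normalize_data_type("Float", "quantity")
#' normalize_data_type("Integer", "count")
#' normalize_data_type("Date")
#' @export
normalize_data_type <- function(source_type,
                                semantic_hint = c("none", "quantity",
                                                  "code", "count")) {
  semantic_hint <- match.arg(semantic_hint)
  known <- c("Float", "Integer", "Text", "String", "Date", "Boolean")
  if (!is.character(source_type) || length(source_type) != 1L ||
      !source_type %in% known) {
    abort(sprintf("unknown source data-type label %s (expected one of %s)",
                  deparse(source_type), paste(known, collapse = ", ")))
  }
  if (semantic_hint == "quantity" &&
      source_type %in% c("Float", "Integer", "Text")) return("Quantity")
  if (semantic_hint == "code" &&
      source_type %in% c("String", "Text", "Integer")) return("Code")
  if (semantic_hint == "count" &&
      source_type %in% c("Integer", "Float")) return("Count")
  switch(source_type,
         Float = "Quantity", Integer = "Count", Text = "Text",
         String = "Text", Date = "Date", Boolean = "Boolean")
}

#' Materialize inherited concepts
#'
#' Replaces every inheritance stub by a full copy of its source concept's
#' payload (data type, codes, description, group path) while preserving the
#' stub's identity and inheritance origin. Chained inheritance is followed;
#' cycles and dangling references are errors. The operation is idempotent and
#' leaves per-dataset concept counts unchanged, so a shared concept still
#' counts once in each dataset inheriting it.
#'
#' @param repo a [concept_repository()]
#' @return the repository with all inherited concepts materialized
#' @export
resolve_inheritance <- function(repo) {
  stopifnot(inherits(repo, "concept_repository"))
  lookup <- function(ds_id, co_id) {
    ds <- repo$datasets[[ds_id]]
    if (is.null(ds)) {
      abort(sprintf("inheritance reference to unknown dataset '%s'", ds_id))
    }
    for (co in ds$concepts) if (co$id == co_id) return(co)
    abort(sprintf("inheritance reference to missing concept '%s' in dataset '%s'",
                  co_id, ds_id))
  }
  resolve_one <- function(co, ds_id, seen) {
    if (!is.list(co$origin)) return(co)
    key <- paste(ds_id, co$id, sep = SEP)
    if (key %in% seen) {
      abort(sprintf("inheritance cycle involving concept '%s' (dataset '%s')",
                    co$id, ds_id))
    }
    src <- lookup(co$origin$dataset, co$origin$concept)
    src <- resolve_one(src, co$origin$dataset, c(seen, key))
    out <- co
    out$data_type <- src$data_type
    out$codes <- src$codes
    out$description <- src$description
    out$group_path <- src$group_path
    if (identical(out$name, out$id) && !identical(src$name, src$id)) {
      out$name <- src$name
    }
    out
  }
  repo$datasets <- lapply(repo$datasets, function(ds) {
    ds$concepts <- lapply(ds$concepts, resolve_one, ds_id = ds$id,
                          seen = character())
    ds
  })
  repo
}

#' Summarize a concept repository
#'
#' Counts concepts per use-case dataset and the fraction carrying codes from
#' a UMLS-type system. Shared concepts (inherited from a basic dataset) count
#' once per use case, matching how overall coverage totals are reported; the
#' basic dataset itself is excluded from the totals.
#'
#' @param repo a [concept_repository()] (inheritance is resolved internally)
#' @param umls_systems canonical system names treated as UMLS-type for the
#'   code-availability statistic
#' @return list with a per-dataset tibble `datasets` and scalars
#'   `n_concepts`, `n_umls_coded`, `umls_coded_pct`
#' @export
repository_summary <- function(repo, umls_systems = c("UMLS", "FAKE-UMLS")) {
  repo <- resolve_inheritance(repo)
  usecase <- keep(repo$datasets, function(ds) ds$use_case != "basic")
  per <- map(usecase, function(ds) {
    has <- vapply(ds$concepts, function(co) {
      any(co$codes$system %in% umls_systems)
    }, logical(1))
    tibble(dataset = ds$id, use_case = ds$use_case,
           n_concepts = length(ds$concepts),
           n_umls_coded = sum(has))
  })
  tab <- bind_rows(per)
  n <- sum(tab$n_concepts)
  k <- sum(tab$n_umls_coded)
  list(datasets = tab, n_concepts = n, n_umls_coded = k,
       umls_coded_pct = pct_of(k, n))
}

#' @export
print.concept_repository <- function(x, ...) {
  cat(sprintf("<concept_repository> project '%s', %d dataset(s)\n",
              x$project_id, length(x$datasets)))
  for (ds in x$datasets) {
    cat(sprintf("  %s [%s]: %d concept(s)\n", ds$id, ds$use_case,
                length(ds$concepts)))
  }
  invisible(x)
}
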