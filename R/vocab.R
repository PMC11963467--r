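#' @name vocab
#' @title Cross-terminology code expansion
#'
#' @description
#' Trial concepts are annotated mostly with UMLS concept identifiers, while
#' CDA template bindings use LOINC, ICD-10, ATC and other systems. The
#' crosswalk emulates the OMOP vocabulary's standard-concept mechanism: a
#' concept table assigns every (system, code) pair to a vocabulary concept
#' key and flags standard concepts; a relationship table links source
#' concepts to standard concepts via the `"Maps to"` relationship. Expansion
#' follows `"Maps to"` exactly one hop from each source code to its standard
#' key(s) and then fans out to every code attached to those standard keys —
#' synonym fan-out is by shared standard key, never by chaining
#' relationships, and no transitive closure is computed.
NULL

#' Construct a vocabulary crosswalk
#'
#' @param concepts tibble/data.frame with columns
#'   `concept_key`, `system`, `code`, `standard` (logical); (system, code)
#'   pairs must be unique
#' @param relationships tibble/data.frame with columns
#'   `source_key`, `target_key`, `relationship`; keys must exist in
#'   `concepts`. `"Maps to"` rows whose target is not standard are dropped
#'   with a message; other relationship labels are retained but never
#'   traversed.
#' @return object of class `crosswalk`
#' @export
crosswalk <- function(concepts, relationships) {
  need_c <- c("concept_key", "system", "code", "standard")
  need_r <- c("source_key", "target_key", "relationship")
  if (!all(need_c %in% names(concepts))) {
    abort(sprintf("concept table needs columns %s",
                  paste(need_c, collapse = ", ")))
  }
  if (!all(need_r %in% names(relationships))) {
    abort(sprintf("relationship table needs columns %s",
                  paste(need_r, collapse = ", ")))
  }
  concepts <- tibble(
    concept_key = as.character(concepts$concept_key),
    system = canonical_system(as.character(concepts$system)),
    code = trimws(as.character(concepts$code)),
    standard = as.logical(concepts$standard)
  )
  dup <- duplicated(concepts[c("system", "code")])
  if (any(dup)) {
    abort(sprintf("duplicate (system, code) row(s) in concept table: %s",
                  paste(code_keys(concepts[dup, ])[1:min(3, sum(dup))],
                        collapse = "; ")))
  }
  relationships <- tibble(
    source_key = as.character(relationships$source_key),
    target_key = as.character(relationships$target_key),
    relationship = as.character(relationships$relationship)
  )
  known <- unique(concepts$concept_key)
  bad <- !(relationships$source_key %in% known &
             relationships$target_key %in% known)
  if (any(bad)) {
    abort(sprintf("relationship row(s) reference unknown concept key(s): %s",
                  paste(utils::head(paste0(
                    relationships$source_key[bad], " -> ",
                    relationships$target_key[bad]), 3), collapse = "; ")))
  }
  std_keys <- unique(concepts$concept_key[concepts$standard])
  maps_to <- relationships$relationship == "Maps to"
  nonstd <- maps_to & !(relationships$target_key %in% std_keys)
  if (any(nonstd)) {
    inform(sprintf("dropping %d \"Maps to\" edge(s) with non-standard targets",
                   sum(nonstd)))
    relationships <- relationships[!nonstd, , drop = FALSE]
  }
  structure(list(concepts = concepts, relationships = relationships),
            class = "crosswalk")
}

#' Load a crosswalk from CSV files
#'
#' @param concept_csv path to a CSV with header
#'   `concept_key,system,code,standard`
#' @param relationship_csv path to a CSV with header
#'   `source_key,target_key,relationship`
#' @return a [crosswalk()]
#' @export
load_crosswalk <- function(concept_csv, relationship_csv) {
  cc <- read.csv(concept_csv, stringsAsFactors = FALSE,
                 colClasses = "character")
  rr <- read.csv(relationship_csv, stringsAsFactors = FALSE,
                 colClasses = "character")
  if ("standard" %in% names(cc)) {
    cc$standard <- toupper(trimws(cc$standard)) %in% c("TRUE", "T", "1", "YES")
  }
  crosswalk(cc, rr)
}

#' Expand a concept's codes across code systems
#'
#' For every source code of the concept that is present in the crosswalk, its
#' `"Maps to"` standard key(s) are collected (a source code lying on a
#' standard key counts as its own standard key), and all codes of all systems
#' attached to those standard keys are emitted. The result is the union of
#' the emitted codes with the concept's own codes, ordered by
#' (system, code). Source codes absent from the crosswalk contribute only
#' themselves.
#'
#' @param concept a [concept()] (or any object with a `$codes` code table
#'   and an `$id`)
#' @param cw a [crosswalk()]
#' @return object of class `expanded_code_set` with fields `concept_id`,
#'   `codes` (code table) and `trace` (tibble mapping every emitted code back
#'   to the source code and standard key it came from)
#' @export
expand_codes <- function(concept, cw) {
  stopifnot(inherits(cw, "crosswalk"))
  src <- concept$codes
  trace <- tibble(source_system = character(), source_code = character(),
                  standard_key = character(), system = character(),
                  code = character())
  if (nrow(src) > 0L) {
    ctab <- cw$concepts
    maps_to <- cw$relationships[cw$relationships$relationship == "Maps to", ,
                                drop = FALSE]
    pieces <- list()
    for (i in seq_len(nrow(src))) {
      hit <- ctab[ctab$system == src$system[i] & ctab$code == src$code[i], ,
                  drop = FALSE]
      # identity row: every source code maps to itself
      pieces[[length(pieces) + 1L]] <- tibble(
        source_system = src$system[i], source_code = src$code[i],
        standard_key = NA_character_, system = src$system[i],
        code = src$code[i])
      if (nrow(hit) == 0L) next
      keys <- unique(hit$concept_key)
      std <- unique(c(
        maps_to$target_key[maps_to$source_key %in% keys],
        keys[keys %in% ctab$concept_key[ctab$standard]]
      ))
      if (length(std) == 0L) next
      emitted <- ctab[ctab$concept_key %in% std, , drop = FALSE]
      pieces[[length(pieces) + 1L]] <- tibble(
        source_system = src$system[i], source_code = src$code[i],
        standard_key = emitted$concept_key, system = emitted$system,
        code = emitted$code)
    }
    trace <- bind_rows(pieces)
  }
  codes <- code_tbl(trace$system, trace$code)
  trace <- trace[order(trace$source_system, trace$source_code, trace$system,
                       trace$code, method = "radix"), , drop = FALSE]
  structure(list(concept_id = concept$id, codes = codes, trace = trace),
            class = "expanded_code_set")
}
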