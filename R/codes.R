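#' Canonical short names for terminology code systems
#'
#' Building-block repositories mix raw OIDs and human short names when naming
#' code systems. All comparisons in this package are performed on a canonical
#' short name, obtained by looking raw identifiers up in a small registry of
#' well-known OIDs. Unknown identifiers pass through unchanged (after
#' whitespace trimming), so synthetic systems such as `"FAKE-UMLS"` are
#' preserved verbatim.
#'
#' @param system character vector of code-system identifiers (OIDs or names)
#' @return character vector of canonical short names
#' @examples
#' canonical_system(c("2.16.840.1.113883.6.1", "SNOMED-CT", "FAKE-UMLS"))
#' @export
canonical_system <- function(system) {
  x <- trimws(system)
  hit <- match(x, code_system_registry$oid)
  out <- ifelse(is.na(hit), x, code_system_registry$short[hit])
  alias <- match(toupper(out), toupper(code_system_registry$short))
  ifelse(is.na(alias), out, code_system_registry$short[alias])
}

# OID <-> short-name registry for the systems that appear in CDA template
# bindings and trial concept repositories.
code_system_registry <- data.frame(
  oid = c(
    "2.16.840.1.113883.6.1",    # LOINC
    "2.16.840.1.113883.6.96",   # SNOMED CT
    "2.16.840.1.113883.6.3",    # ICD-10 (WHO)
    "2.16.840.1.113883.6.86",   # UMLS
    "2.16.840.1.113883.6.88",   # RxNorm
    "2.16.840.1.113883.6.73",   # ATC
    "2.16.840.1.113883.6.254"   # ICF
  ),
  short = c("LOINC", "SNOMED-CT", "ICD-10", "UMLS", "RxNorm", "ATC", "ICF"),
  stringsAsFactors = FALSE
)

#' Build a normalized code table
#'
#' A set of terminology codes is represented as a tibble with columns
#' `system`, `code`, `display`. Systems are canonicalized via
#' [canonical_system()], whitespace is trimmed, duplicate (system, code) pairs
#' are collapsed, and rows are sorted by (system, code) so that two code sets
#' with the same content are identical tibbles.
#'
#' @param system,code,display character vectors (recycled to common length);
#'   `display` may be `NA`
#' @return tibble with columns `system`, `code`, `display`
#' @export
code_tbl <- function(system = character(), code = character(),
                     display = NA_character_) {
  if (length(system) == 0L && length(code) == 0L) {
    return(tibble(system = character(), code = character(),
                  display = character()))
  }
  tb <- tibble(system = as.character(system), code = as.character(code),
               display = as.character(display))
  if (any(is.na(tb$system)) || any(is.na(tb$code))) {
    abort("code system and code must not be NA")
  }
  tb$system <- canonical_system(tb$system)
  tb$code <- trimws(tb$code)
  if (any(!nzchar(tb$system)) || any(!nzchar(tb$code))) {
    abort("code system and code must be non-empty")
  }
  tb <- tb[!duplicated(tb[c("system", "code")]), , drop = FALSE]
  tb[order(tb$system, tb$code, method = "radix"), , drop = FALSE]
}

# internal: composite key for (system, code) equality
code_keys <- function(tb) paste(tb$system, tb$code, sep = SEP)
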