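#' @name decor_io
#' @title DECOR-dialect XML input/output
#'
#' @description
#' The package reads and writes a documented subset of the DECOR XML format
#' used by template-management tooling. Full schema compatibility is not
#' promised, but the subset uses the same element and attribute vocabulary
#' (`dataset`, `concept`, `code`/`codeSystem`, `template`, `valueSet`,
#' `templateAssociation`, `effectiveDate`) so that real exports restricted to
#' these elements parse. All files are UTF-8; effective dates are ISO-8601
#' strings compared lexicographically as version keys.
#'
#' ## Concept repository
#' ```xml
#' <decor project="inventory">
#'   <dataset id="ds-feas" name="Feasibility" useCase="feasibility">
#'     <concept id="F001" name="Albumin" dataType="Quantity">
#'       <desc>Serum albumin measurement</desc>
#'       <group>Laboratory findings</group>
#'       <code code="CU0001" codeSystem="FAKE-UMLS" displayName="Albumin"/>
#'     </concept>
#'     <concept id="B001" inheritDataset="ds-basic" inheritConcept="B001"/>
#'   </dataset>
#' </decor>
#' ```
#' Repeated `<group>` children form the ordered group path. An inheritance
#' stub carries only `inheritDataset`/`inheritConcept`.
#'
#' ## Template repository (BBR)
#' ```xml
#' <decor repository="bbr-main">
#'   <template id="1.2.99.1.10" effectiveDate="2021-01-01T00:00:00"
#'             name="Laboratory Observation">
#'     <element id="e-code" path="hl7:code" contentKind="coded">
#'       <vocabulary valueSet="vs-lab"/>
#'     </element>
#'     <element id="e-value" path="hl7:value" contentKind="quantity"/>
#'   </template>
#'   <valueSet id="vs-lab" effectiveDate="2021-06-01T00:00:00">
#'     <code code="L0001" codeSystem="FAKE-LOINC"/>
#'   </valueSet>
#'   <documentType id="dt-lab" name="Lab report" status="Normative">
#'     <templateRef ref="1.2.99.1.10"/>
#'   </documentType>
#' </decor>
#' ```
#' A fixed binding is written as a `<code>` child of the element. A template
#' is normative when referenced by at least one document type whose status is
#' `"Normative"`; if the file declares no document types at all, every
#' template is taken as normative.
#'
#' ## Template associations
#' ```xml
#' <decor project="mappings">
#'   <templateAssociation concept="F001" template="1.2.99.1.10"
#'                        effectiveDate="2021-01-01T00:00:00"
#'                        provenance="automatic">
#'     <element id="e-code"/>
#'     <element id="e-value"/>
#'     <qualifier code="L0001" codeSystem="FAKE-LOINC"/>
#'   </templateAssociation>
#' </decor>
#' ```
NULL

# internal: required attribute with a schema error naming the element
req_attr <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) {
    abort(sprintf("schema error: <%s> is missing required attribute '%s'",
                  xml2::xml_name(node), attr))
  }
  v
}

read_decor_xml <- function(xml_text) {
  tryCatch(
    xml2::read_xml(xml_text, encoding = "UTF-8"),
    error = function(e) {
      abort(sprintf("malformed XML: %s", conditionMessage(e)))
    }
  )
}

parse_code_nodes <- function(parent) {
  nodes <- xml2::xml_find_all(parent, "./code")
  if (length(nodes) == 0L) return(code_tbl())
  code_tbl(
    system = vapply(nodes, req_attr, character(1), attr = "codeSystem"),
    code = vapply(nodes, req_attr, character(1), attr = "code"),
    display = vapply(nodes, xml2::xml_attr, character(1), attr = "displayName")
  )
}

#' Parse a concept repository from DECOR-dialect XML
#'
#' @param xml_text XML string, file path, or connection accepted by
#'   [xml2::read_xml()]
#' @param quiet suppress the parse log (per-dataset concept counts)
#' @return a [concept_repository()]
#' @export
parse_concept_repository <- function(xml_text, quiet = FALSE) {
  doc <- read_decor_xml(xml_text)
  project <- req_attr(xml2::xml_root(doc), "project")
  ds_nodes <- xml2::xml_find_all(doc, "/decor/dataset")
  datasets <- map(ds_nodes, function(ds_node) {
    ds_id <- req_attr(ds_node, "id")
    co_nodes <- xml2::xml_find_all(ds_node, "./concept")
    if (length(co_nodes) == 0L) {
      warn(sprintf("dataset '%s' contains no concepts", ds_id))
    }
    concepts <- map(co_nodes, function(co_node) {
      co_id <- req_attr(co_node, "id")
      inh_ds <- xml2::xml_attr(co_node, "inheritDataset")
      if (!is.na(inh_ds)) {
        return(concept(
          id = co_id,
          origin = list(dataset = inh_ds,
                        concept = req_attr(co_node, "inheritConcept"))))
      }
      groups <- xml2::xml_text(xml2::xml_find_all(co_node, "./group"))
      desc <- xml2::xml_text(xml2::xml_find_first(co_node, "./desc"))
      concept(
        id = co_id,
        name = xml2::xml_attr(co_node, "name") %|NA|% co_id,
        data_type = req_attr(co_node, "dataType"),
        codes = parse_code_nodes(co_node),
        group_path = if (length(groups)) groups else "General",
        description = if (is.na(desc)) "" else desc
      )
    })
    concept_dataset(
      id = ds_id,
      name = xml2::xml_attr(ds_node, "name") %|NA|% ds_id,
      use_case = req_attr(ds_node, "useCase"),
      concepts = concepts
    )
  })
  repo <- concept_repository(project, datasets)
  if (!quiet) {
    counts <- vapply(repo$datasets, function(d) length(d$concepts), integer(1))
    inform(sprintf("parsed concept repository '%s': %d dataset(s), %s concepts",
                   project, length(counts),
                   paste(counts, collapse = "+")))
  }
  repo
}

#' Parse a template repository (BBR) from DECOR-dialect XML
#'
#' @inheritParams parse_concept_repository
#' @return a [template_repository()]
#' @export
parse_template_repository <- function(xml_text, quiet = FALSE) {
  doc <- read_decor_xml(xml_text)
  repo_id <- req_attr(xml2::xml_root(doc), "repository")

  dt_nodes <- xml2::xml_find_all(doc, "/decor/documentType")
  normative_ids <- character()
  have_doc_types <- length(dt_nodes) > 0L
  for (dt in dt_nodes) {
    if (identical(xml2::xml_attr(dt, "status"), "Normative")) {
      refs <- xml2::xml_find_all(dt, "./templateRef")
      normative_ids <- c(normative_ids,
                         vapply(refs, req_attr, character(1), attr = "ref"))
    }
  }

  value_sets <- map(xml2::xml_find_all(doc, "/decor/valueSet"), function(vn) {
    value_set(req_attr(vn, "id"), req_attr(vn, "effectiveDate"),
              parse_code_nodes(vn))
  })

  templates <- map(xml2::xml_find_all(doc, "/decor/template"), function(tn) {
    tid <- req_attr(tn, "id")
    elements <- map(xml2::xml_find_all(tn, "./element"), function(en) {
      vocab <- xml2::xml_find_first(en, "./vocabulary")
      fixed <- xml2::xml_find_first(en, "./code")
      binding <- list(kind = "none")
      if (!inherits(vocab, "xml_missing")) {
        binding <- list(kind = "valueset",
                        valueset_id = req_attr(vocab, "valueSet"))
      } else if (!inherits(fixed, "xml_missing")) {
        binding <- list(kind = "fixed",
                        system = req_attr(fixed, "codeSystem"),
                        code = req_attr(fixed, "code"),
                        display = xml2::xml_attr(fixed, "displayName"))
      }
      template_element(req_attr(en, "id"), req_attr(en, "path"),
                       req_attr(en, "contentKind"), binding)
    })
    cda_template(
      template_id = tid,
      effective_date = req_attr(tn, "effectiveDate"),
      name = xml2::xml_attr(tn, "name") %|NA|% tid,
      elements = elements,
      normative = !have_doc_types || tid %in% normative_ids
    )
  })

  repo <- template_repository(repo_id, templates, value_sets)
  if (!quiet) {
    inform(sprintf(
      "parsed template repository '%s': %d template(s) (%d normative), %d value set version(s)",
      repo_id, length(repo$templates),
      sum(vapply(repo$templates, function(t) t$normative, logical(1))),
      length(repo$value_sets)))
  }
  repo
}

#' Parse a template-association project file
#'
#' @inheritParams parse_concept_repository
#' @return an [association_document()]
#' @export
parse_associations <- function(xml_text) {
  doc <- read_decor_xml(xml_text)
  project <- req_attr(xml2::xml_root(doc), "project")
  nodes <- xml2::xml_find_all(doc, "/decor/templateAssociation")
  assocs <- map(nodes, function(an) {
    el_nodes <- xml2::xml_find_all(an, "./element")
    qn <- xml2::xml_find_first(an, "./qualifier")
    qualifier <- NULL
    if (!inherits(qn, "xml_missing")) {
      qualifier <- list(system = req_attr(qn, "codeSystem"),
                        code = req_attr(qn, "code"),
                        display = xml2::xml_attr(qn, "displayName"))
    }
    template_association(
      concept_id = req_attr(an, "concept"),
      template_id = req_attr(an, "template"),
      effective_date = req_attr(an, "effectiveDate"),
      element_ids = vapply(el_nodes, req_attr, character(1), attr = "id"),
      qualifier = qualifier,
      provenance = req_attr(an, "provenance")
    )
  })
  association_document(project, assocs)
}

#' Validate association targets against repositories
#'
#' Checks that every association references an existing concept and a
#' resolvable template element; associations pointing at non-normative
#' templates are reported.
#'
#' @param doc an [association_document()]
#' @param concept_repo a [concept_repository()]
#' @param template_repos a [template_repository()] or list thereof
#' @return invisibly `doc`; errors on unresolvable references, warns on
#'   non-normative targets
#' @export
validate_associations <- function(doc, concept_repo, template_repos) {
  concept_repo <- resolve_inheritance(concept_repo)
  known_concepts <- unique(unlist(map(concept_repo$datasets, function(ds) {
    vapply(ds$concepts, function(co) co$id, character(1))
  })))
  for (a in doc$associations) {
    if (!a$concept_id %in% known_concepts) {
      abort(sprintf("association references unknown concept '%s'",
                    a$concept_id))
    }
    t <- find_template(template_repos, a$template_id, a$effective_date)
    if (is.null(t)) {
      abort(sprintf("association for '%s' references missing template '%s' (%s)",
                    a$concept_id, a$template_id, a$effective_date))
    }
    eids <- vapply(t$elements, function(el) el$element_id, character(1))
    missing <- setdiff(a$element_ids, eids)
    if (length(missing)) {
      abort(sprintf("association for '%s' references missing element(s) %s of template '%s'",
                    a$concept_id, paste(missing, collapse = ", "),
                    a$template_id))
    }
    if (!t$normative) {
      warn(sprintf("association for '%s' targets non-normative template '%s'",
                   a$concept_id, a$template_id))
    }
  }
  invisible(doc)
}

# ---- writers ---------------------------------------------------------------

add_code_nodes <- function(parent, codes, tag = "code") {
  for (i in seq_len(nrow(codes))) {
    node <- xml2::xml_add_child(parent, tag, code = codes$code[i],
                                codeSystem = codes$system[i])
    if (!is.na(codes$display[i])) {
      xml2::xml_set_attr(node, "displayName", codes$display[i])
    }
  }
}

#' Serialize a concept repository to DECOR-dialect XML
#'
#' @param repo a [concept_repository()]
#' @return XML text (UTF-8, deterministic for a given repository)
#' @export
write_concept_repository <- function(repo) {
  stopifnot(inherits(repo, "concept_repository"))
  doc <- xml2::xml_new_root("decor", project = repo$project_id)
  for (ds in repo$datasets) {
    ds_node <- xml2::xml_add_child(doc, "dataset", id = ds$id, name = ds$name,
                                   useCase = ds$use_case)
    for (co in ds$concepts) {
      if (is.list(co$origin)) {
        xml2::xml_add_child(ds_node, "concept", id = co$id,
                            inheritDataset = co$origin$dataset,
                            inheritConcept = co$origin$concept)
        next
      }
      co_node <- xml2::xml_add_child(ds_node, "concept", id = co$id,
                                     name = co$name, dataType = co$data_type)
      if (nzchar(co$description)) {
        xml2::xml_add_child(co_node, "desc", co$description)
      }
      for (g in co$group_path) xml2::xml_add_child(co_node, "group", g)
      add_code_nodes(co_node, co$codes)
    }
  }
  as.character(doc)
}

#' Serialize a template repository to DECOR-dialect XML
#'
#' Emits one normative and (if needed) one draft document type so that the
#' normative flags survive a round trip.
#'
#' @param repo a [template_repository()]
#' @return XML text
#' @export
write_template_repository <- function(repo) {
  stopifnot(inherits(repo, "template_repository"))
  doc <- xml2::xml_new_root("decor", repository = repo$repository_id)
  for (t in repo$templates) {
    tn <- xml2::xml_add_child(doc, "template", id = t$template_id,
                              effectiveDate = t$effective_date, name = t$name)
    for (el in t$elements) {
      en <- xml2::xml_add_child(tn, "element", id = el$element_id,
                                path = el$path,
                                contentKind = el$content_kind)
      if (el$binding$kind == "valueset") {
        xml2::xml_add_child(en, "vocabulary",
                            valueSet = el$binding$valueset_id)
      } else if (el$binding$kind == "fixed") {
        cn <- xml2::xml_add_child(en, "code", code = el$binding$code,
                                  codeSystem = el$binding$system)
        if (!is.na(el$binding$display)) {
          xml2::xml_set_attr(cn, "displayName", el$binding$display)
        }
      }
    }
  }
  for (v in repo$value_sets) {
    vn <- xml2::xml_add_child(doc, "valueSet", id = v$valueset_id,
                              effectiveDate = v$effective_date)
    add_code_nodes(vn, v$codes)
  }
  norm <- unique(vapply(keep(repo$templates, function(t) t$normative),
                        function(t) t$template_id, character(1)))
  draft <- setdiff(unique(vapply(repo$templates, function(t) t$template_id,
                                 character(1))), norm)
  if (length(norm)) {
    dt <- xml2::xml_add_child(doc, "documentType", id = "dt-normative",
                              name = "Normative documents",
                              status = "Normative")
    for (id in norm) xml2::xml_add_child(dt, "templateRef", ref = id)
  }
  if (length(draft)) {
    dt <- xml2::xml_add_child(doc, "documentType", id = "dt-draft",
                              name = "Draft documents", status = "Draft")
    for (id in draft) xml2::xml_add_child(dt, "templateRef", ref = id)
  }
  as.character(doc)
}

#' Serialize an association document to DECOR-dialect XML
#'
#' `parse_associations(write_associations(doc))` reproduces the association
#' set exactly.
#'
#' @param doc an [association_document()]
#' @return XML text
#' @export
write_associations <- function(doc) {
  stopifnot(inherits(doc, "association_document"))
  root <- xml2::xml_new_root("decor", project = doc$project_id)
  for (a in doc$associations) {
    an <- xml2::xml_add_child(root, "templateAssociation",
                              concept = a$concept_id,
                              template = a$template_id,
                              effectiveDate = a$effective_date,
                              provenance = a$provenance)
    for (eid in a$element_ids) xml2::xml_add_child(an, "element", id = eid)
    if (!is.null(a$qualifier)) {
      qn <- xml2::xml_add_child(an, "qualifier", code = a$qualifier$code,
                                codeSystem = a$qualifier$system)
      if (!is.na(a$qualifier$display)) {
        xml2::xml_set_attr(qn, "displayName", a$qualifier$display)
      }
    }
  }
  as.character(root)
}

#' Fetch a project file over HTTP
#'
#' Thin convenience wrapper: performs a single request and returns the raw
#' XML text unmodified. Errors (HTTP failures, timeouts) are surfaced to the
#' caller and never retried.
#'
#' @param url full URL of the XML export
#' @return character scalar of XML text
#' @export
fetch_project <- function(url) {
  url <- chr1(url, "url")
  con <- url(url, encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  paste(readLines(con, warn = FALSE), collapse = "\n")
}

# internal: NA-coalescing helper for optional XML attributes
`%|NA|%` <- function(x, y) if (is.na(x)) y else x
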