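test_that("concept repositories parse with expected counts and diagnostics", {
  fix <- generate_fixture(elga_preset())
  xml <- write_concept_repository(fix$concepts)
  expect_message(r2 <- parse_concept_repository(xml), "4 dataset")
  counts <- vapply(r2$datasets, function(d) length(d$concepts), integer(1))
  expect_identical(unname(counts[c("ds-feasibility", "ds-recruitment",
                                   "ds-execution")]), c(75L, 149L, 133L))
  # a concept carrying two codes keeps both
  two <- concept_repository("p", list(concept_dataset(
    "d", use_case = "feasibility", concepts = list(
      concept("c1", data_type = "Code",
              codes = code_tbl(c("FAKE-UMLS", "FAKE-SNOMED"),
                               c("CU1", "S1")))))))
  rt <- parse_concept_repository(write_concept_repository(two), quiet = TRUE)
  expect_identical(nrow(rt$datasets$d$concepts[[1]]$codes), 2L)
})

test_that("empty datasets and malformed or incomplete XML are diagnosed", {
  expect_warning(
    parse_concept_repository(
      '<decor project="p"><dataset id="d" useCase="basic"/></decor>',
      quiet = TRUE),
    "no concepts")
  expect_error(parse_concept_repository("<decor><oops"), "malformed XML")
  expect_error(
    parse_concept_repository(
      '<decor project="p"><dataset useCase="basic"/></decor>', quiet = TRUE),
    "missing required attribute 'id'")
})

test_that("template repositories parse bindings, versions, and normative flags", {
  xml <- '
  <decor repository="bbr">
    <template id="1.2.3" effectiveDate="2021-01-01T00:00:00" name="Lab Obs">
      <element id="e1" path="hl7:code" contentKind="coded">
        <vocabulary valueSet="vs1"/>
      </element>
      <element id="e2" path="hl7:value" contentKind="quantity"/>
    </template>
    <template id="1.2.4" effectiveDate="2021-01-01T00:00:00" name="Notes">
      <element id="e1" path="hl7:text" contentKind="narrative_text"/>
    </template>
    <valueSet id="vs1" effectiveDate="2020-01-01T00:00:00">
      <code code="L1" codeSystem="FAKE-LOINC"/>
    </valueSet>
    <valueSet id="vs1" effectiveDate="2021-01-01T00:00:00">
      <code code="L1" codeSystem="FAKE-LOINC"/>
      <code code="L2" codeSystem="FAKE-LOINC"/>
    </valueSet>
    <documentType id="dt" status="Normative"><templateRef ref="1.2.3"/></documentType>
  </decor>'
  repo <- parse_template_repository(xml, quiet = TRUE)
  expect_length(repo$templates, 2L)
  expect_length(repo$value_sets, 2L)   # two versions of one value set id
  lab <- Filter(function(t) t$template_id == "1.2.3", repo$templates)[[1]]
  expect_length(lab$elements, 2L)
  expect_identical(lab$elements[[1]]$binding$kind, "valueset")
  expect_true(lab$normative)
  notes <- Filter(function(t) t$template_id == "1.2.4", repo$templates)[[1]]
  expect_identical(notes$elements[[1]]$content_kind, "narrative_text")
  expect_false(notes$normative)
  # binding to an absent value set is refused
  expect_error(parse_template_repository('
    <decor repository="b">
      <template id="t" effectiveDate="2021" name="x">
        <element id="e" path="hl7:code" contentKind="coded">
          <vocabulary valueSet="missing"/>
        </element>
      </template>
    </decor>'), "missing value set")
})

test_that("association documents round-trip exactly, qualifiers included", {
  a1 <- template_association("c1", "1.2.3", "2021-01-01T00:00:00",
                             c("e1", "e2"),
                             qualifier = list(system = "FAKE-LOINC",
                                              code = "L1"),
                             provenance = "automatic")
  a2 <- template_association("c2", "1.2.4", "2021-01-01T00:00:00", "e1")
  doc <- association_document("proj", list(a1, a2))
  rt <- parse_associations(write_associations(doc))
  expect_identical(rt$associations, doc$associations)
  expect_identical(rt$associations[[1]]$qualifier$code, "L1")
  # empty documents are valid files
  empty <- association_document("proj")
  expect_length(parse_associations(write_associations(empty))$associations, 0L)
  # duplicates collapse with a warning
  expect_warning(association_document("proj", list(a1, a1)), "duplicate")
})

test_that("all three document kinds round-trip on randomized fixtures", {
  withr::with_seed(42, {
    for (i in 1:5) {
      spec <- fixture_spec(seed = 100 + i,
                           n_concepts = c(feasibility = sample(3:12, 1),
                                          recruitment = sample(3:12, 1),
                                          execution = sample(3:12, 1)),
                           n_shared = sample(0:2, 1), frac_matchable = 0.3,
                           frac_mapped = 0.8, frac_structured = 0.7,
                           frac_umls = 0.9)
      fix <- generate_fixture(spec)
      expect_identical(
        parse_concept_repository(write_concept_repository(fix$concepts),
                                 quiet = TRUE),
        fix$concepts)
      expect_identical(
        parse_template_repository(write_template_repository(fix$templates),
                                  quiet = TRUE),
        fix$templates)
      expect_identical(
        parse_associations(write_associations(fix$manual_associations)),
        fix$manual_associations)
    }
  })
})

test_that("sibling record order in the XML does not affect the parsed model", {
  xml_a <- '
  <decor project="p">
    <dataset id="d" useCase="feasibility">
      <concept id="c1" name="one" dataType="Text"><group>G</group></concept>
      <concept id="c2" name="two" dataType="Text"><group>G</group></concept>
    </dataset>
  </decor>'
  xml_b <- sub('(<concept id="c1".*?</concept>)(\\s*)(<concept id="c2".*?</concept>)',
               "\\3\\2\\1", xml_a, perl = TRUE)
  expect_identical(parse_concept_repository(xml_a, quiet = TRUE),
                   parse_concept_repository(xml_b, quiet = TRUE))
})

test_that("the YAML report has the fixed key schema and round-trips", {
  fix <- generate_fixture(elga_preset())
  rep <- run_fixture_pipeline(fix)$report
  txt <- write_report_yaml(rep)
  parsed <- yaml::yaml.load(txt)
  expect_identical(parsed$overall$concepts, 357L)
  expect_identical(parsed$overall$mapped, 315L)
  expect_identical(parsed$overall$mapped_pct, 88L)
  expect_identical(parsed$overall$structured, 275L)
  expect_identical(parsed$overall$structured_pct, 77L)
  expect_setequal(names(parsed$use_cases),
                  c("feasibility", "recruitment", "execution"))
  expect_identical(names(parsed$overall),
                   sort(names(parsed$overall)))
  # parse -> compare field-for-field with the canonical list form
  canon <- rapply(report_as_list(rep), unclass, how = "list")
  expect_equal(parsed, canon, ignore_attr = TRUE)
  # empty repositories yield a zero-count overall block
  empty_rep <- analyze_coverage(
    concept_repository("p", list()), list(), list())
  ytxt <- write_report_yaml(empty_rep)
  expect_identical(yaml::yaml.load(ytxt)$overall$concepts, 0L)
})
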