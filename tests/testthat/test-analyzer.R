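analyzer_repo <- function() {
  template_repository("bbr", templates = list(
    cda_template("t-struct", "2021-01-01T00:00:00", "Entry", list(
      template_element("e-q", "hl7:value", "quantity"),
      template_element("e-c", "hl7:code", "coded",
                       list(kind = "valueset", valueset_id = "vs")),
      template_element("e-v", "hl7:value2", "quantity"))),
    cda_template("t-text", "2021-01-01T00:00:00", "Uncoded", list(
      template_element("e-t", "hl7:text", "narrative_text"))),
    cda_template("t-draft", "2021-01-01T00:00:00", "Draft", list(
      template_element("e-q", "hl7:value", "quantity")),
      normative = FALSE)),
    value_sets = list(value_set("vs", "2021-01-01T00:00:00",
                                code_tbl("FAKE-LOINC", "L1"))))
}

test_that("elements classify as structured unless they are narrative text", {
  expect_identical(classify_element(
    template_element("e", "hl7:value", "quantity")), "structured")
  expect_identical(classify_element(
    template_element("e", "hl7:text", "narrative_text")), "free_text")
  expect_identical(classify_element(
    template_element("e", "hl7:code", "coded",
                     list(kind = "valueset", valueset_id = "v"))),
    "structured")
  expect_identical(classify_element(
    template_element("e", "hl7:time", "datetime")), "structured")
})

test_that("structured targets take precedence over free-text targets", {
  repos <- analyzer_repo()
  mix <- list(
    template_association("c1", "t-text", "2021-01-01T00:00:00", "e-t"),
    template_association("c1", "t-struct", "2021-01-01T00:00:00", "e-q"))
  expect_identical(classify_concept("c1", mix, repos), "mapped_structured")
  expect_identical(classify_concept("c9", mix, repos), "unmapped")
  only_text <- list(
    template_association("c1", "t-text", "2021-01-01T00:00:00", "e-t"))
  expect_identical(classify_concept("c1", only_text, repos),
                   "mapped_free_text")
  # paired generic-template association: both elements are structured
  paired <- list(template_association(
    "c1", "t-struct", "2021-01-01T00:00:00", c("e-c", "e-v"),
    qualifier = list(system = "FAKE-LOINC", code = "L1"),
    provenance = "automatic"))
  expect_identical(classify_concept("c1", paired, repos), "mapped_structured")
})

test_that("unresolvable targets error; non-normative targets are flagged and ignored", {
  repos <- analyzer_repo()
  bad <- list(template_association("c1", "t-missing", "2021", "e"))
  expect_error(classify_concept("c1", bad, repos), "missing template")
  bad_el <- list(template_association("c1", "t-text", "2021-01-01T00:00:00",
                                      "e-nope"))
  expect_error(classify_concept("c1", bad_el, repos), "missing element")
  draft <- list(template_association("c1", "t-draft", "2021-01-01T00:00:00",
                                     "e-q"))
  expect_warning(st <- classify_concept("c1", draft, repos), "non-normative")
  expect_identical(st, "unmapped")
})

test_that("printed percentages follow half-up integer rounding", {
  cases <- list(c(71, 75, 95), c(135, 149, 91), c(109, 133, 82),
                c(315, 357, 88), c(275, 357, 77), c(67, 75, 89),
                c(119, 149, 80), c(89, 133, 67))
  for (cs in cases) expect_identical(pct_of(cs[1], cs[2]), as.integer(cs[3]))
  expect_identical(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1L, 2L, 3L, -1L))
})

test_that("the report is additive: use-case rows sum group rows, overall sums use cases", {
  withr::with_seed(13, {
    for (i in 1:8) {
      fm <- stats::runif(1, 0.5, 1)
      fs <- stats::runif(1, 0.3, 1)
      fu <- stats::runif(1, 0.5, 1)
      spec <- fixture_spec(seed = 200 + i,
                           n_concepts = c(feasibility = sample(5:25, 1),
                                          recruitment = sample(5:25, 1),
                                          execution = sample(5:25, 1)),
                           n_shared = sample(0:3, 1),
                           frac_matchable = stats::runif(1) * 0.9 *
                             min(fm * fs, fu),
                           frac_mapped = fm, frac_structured = fs,
                           frac_umls = fu)
      rep <- run_fixture_pipeline(generate_fixture(spec))$report
      tot <- function(rows, f) sum(vapply(rows, function(r) r[[f]], integer(1)))
      for (u in rep$use_cases) {
        for (f in c("concepts", "mapped", "structured")) {
          expect_identical(tot(u$groups, f), u$row[[f]])
        }
        expect_true(u$row$structured <= u$row$mapped)
        expect_true(u$row$mapped <= u$row$concepts)
      }
      rows <- lapply(rep$use_cases, function(u) u$row)
      for (f in c("concepts", "mapped", "structured")) {
        expect_identical(tot(rows, f), rep$overall[[f]])
      }
    }
  })
})

test_that("adding an association never decreases mapped or structured counts", {
  fix <- generate_fixture(fixture_spec(
    seed = 9, n_concepts = c(feasibility = 15, recruitment = 10,
                             execution = 10),
    n_shared = 2, frac_mapped = 0.6, frac_structured = 0.5,
    frac_matchable = 0.2, frac_umls = 0.8))
  base <- analyze_coverage(fix$concepts, fix$manual_associations,
                           fix$templates)
  gt <- fix$ground_truth
  unmapped <- gt$concept_id[gt$status == "unmapped"][1]
  uc_idx <- match(gt$use_case[gt$concept_id == unmapped][1],
                  c("feasibility", "recruitment", "execution"))
  extra <- template_association(unmapped, sprintf("1.2.99.%d.20", uc_idx),
                                "2021-01-01T00:00:00", "e-val")
  more <- analyze_coverage(fix$concepts,
                           list(fix$manual_associations, extra),
                           fix$templates)
  expect_true(more$overall$mapped >= base$overall$mapped)
  expect_true(more$overall$structured >= base$overall$structured)
  expect_true(more$overall$mapped > base$overall$mapped)
})

test_that("identical inputs produce byte-identical YAML", {
  fix <- generate_fixture(fixture_spec(
    seed = 3, n_concepts = c(feasibility = 12, recruitment = 12,
                             execution = 12),
    n_shared = 2))
  y1 <- write_report_yaml(run_fixture_pipeline(fix)$report)
  y2 <- write_report_yaml(run_fixture_pipeline(generate_fixture(
    fixture_spec(seed = 3, n_concepts = c(feasibility = 12, recruitment = 12,
                                          execution = 12),
                 n_shared = 2)))$report)
  expect_identical(y1, y2)
})

test_that("a repository with no associations reports all zeros", {
  fix <- generate_fixture(fixture_spec(
    seed = 2, n_concepts = c(feasibility = 6, recruitment = 6, execution = 6),
    n_shared = 0))
  rep <- analyze_coverage(fix$concepts, list(), fix$templates)
  expect_identical(rep$overall$concepts, 18L)
  expect_identical(rep$overall$mapped, 0L)
  expect_identical(rep$overall$structured_pct, 0L)
  for (u in rep$use_cases) {
    expect_identical(u$row$mapped, 0L)
    for (g in u$groups) expect_identical(g$mapped, 0L)
  }
})
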