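tiny_repo <- function() {
  template_repository(
    "bbr",
    templates = list(
      cda_template("1.2.3", "2021-01-01T00:00:00", "Lab Obs", list(
        template_element("e-code", "hl7:code", "coded",
                         list(kind = "valueset", valueset_id = "vs1")),
        template_element("e-value", "hl7:value", "quantity"))),
      cda_template("1.2.4", "2021-01-01T00:00:00", "Entry", list(
        template_element("e1", "hl7:code", "coded",
                         list(kind = "fixed", system = "FAKE-LOINC",
                              code = "L9"))))),
    value_sets = list(
      value_set("vs1", "2020-01-01T00:00:00",
                code_tbl(rep("FAKE-LOINC", 2), c("L1", "L2"))),
      value_set("vs1", "2021-01-01T00:00:00",
                code_tbl(rep("FAKE-LOINC", 3), c("L1", "L2", "L3")))))
}

expanded_for <- function(...) {
  codes <- c(...)
  structure(list(concept_id = "c1",
                 codes = code_tbl(rep("FAKE-LOINC", length(codes)), codes),
                 trace = NULL),
            class = "expanded_code_set")
}

test_that("the code index agrees with a linear scan of the repository", {
  repo <- tiny_repo()
  idx <- index_codes(repo)
  # 2 + 3 value-set entries plus one fixed binding
  expect_identical(nrow(idx), 6L)
  expect_identical(sum(idx$via == "fixed"), 1L)
  # five value-set codes share element e-code of the lab template
  expect_identical(sum(idx$element_id == "e-code"), 5L)
  # single fixed binding repo
  one <- template_repository("b", list(
    cda_template("t", "2021", "x", list(
      template_element("e", "hl7:code", "coded",
                       list(kind = "fixed", system = "FAKE-LOINC",
                            code = "L1"))))))
  expect_identical(nrow(index_codes(one)), 1L)
})

test_that("matching yields one pending candidate per concept with hits", {
  repo <- tiny_repo()
  idx <- index_codes(repo)
  cands <- match_concepts(list(expanded_for("L1")), idx)
  expect_length(cands, 1L)
  expect_identical(cands[[1]]$status, "pending")
  expect_identical(nrow(cands[[1]]$occurrences), 2L)  # both vs versions
  # no hits -> absent from output
  expect_length(match_concepts(list(expanded_for("Lxxx")), idx), 0L)
})

test_that("consolidation collapses value-set versions and groups codes, idempotently", {
  repo <- tiny_repo()
  idx <- index_codes(repo)
  cands <- match_concepts(list(expanded_for("L1", "L2", "L9")), idx)
  cons <- consolidate_candidates(cands)
  expect_length(cons, 1L)
  occ <- cons[[1]]$occurrences
  # one grouped value-set occurrence (latest version) + one fixed occurrence
  expect_identical(nrow(occ), 2L)
  vs_row <- occ[occ$via == "valueset", ]
  expect_identical(vs_row$valueset_date, "2021-01-01T00:00:00")
  expect_identical(nrow(vs_row$codes[[1]]), 2L)
  # idempotent, and the matched concept set is unchanged
  expect_identical(consolidate_candidates(cons), cons)
  expect_identical(vapply(cons, function(x) x$concept_id, character(1)),
                   vapply(cands, function(x) x$concept_id, character(1)))
  # a candidate with a single occurrence passes through unchanged in content
  single <- consolidate_candidates(match_concepts(list(expanded_for("L9")), idx))
  expect_identical(nrow(single[[1]]$occurrences), 1L)
})

test_that("status transitions are pending -> accepted/rejected only", {
  cands <- match_concepts(list(expanded_for("L1")), index_codes(tiny_repo()))
  acc <- set_candidate_status(cands, "accepted")
  expect_identical(acc[[1]]$status, "accepted")
  expect_error(set_candidate_status(acc, "rejected", reason = "no"),
               "transitions only from pending")
  expect_error(set_candidate_status(cands, "rejected"), "reason")
})

test_that("accepted candidates become associations; generic templates pair code+value", {
  repo <- tiny_repo()
  cands <- consolidate_candidates(
    match_concepts(list(expanded_for("L1", "L9")), index_codes(repo)))
  acc <- set_candidate_status(cands, "accepted")
  assocs <- to_associations(acc, repo)
  expect_length(assocs, 2L)
  paired <- Filter(function(a) a$template_id == "1.2.3", assocs)[[1]]
  expect_identical(paired$element_ids, c("e-code", "e-value"))
  expect_identical(paired$qualifier$code, "L1")
  expect_identical(paired$provenance, "automatic")
  plain <- Filter(function(a) a$template_id == "1.2.4", assocs)[[1]]
  expect_identical(plain$element_ids, "e1")
  expect_null(plain$qualifier)
  # rejected candidates contribute nothing; pending ones are an error
  rej <- set_candidate_status(cands, "rejected", reason = "not equivalent")
  expect_length(to_associations(rej, repo), 0L)
  expect_error(to_associations(cands, repo), "pending")
})

test_that("matching equals the brute-force quadruple-loop oracle on random scenes", {
  withr::with_seed(23, {
    for (i in 1:30) {
      sc <- random_match_scene(n_concepts = sample(3:10, 1))
      got <- candidates_as_rows(match_concepts(sc$expanded,
                                               index_codes(sc$repo)))
      want <- oracle_match(sc$expanded, sc$repo)
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE)
    }
  })
})

test_that("consolidation never changes which concepts are matched (random scenes)", {
  withr::with_seed(31, {
    for (i in 1:10) {
      sc <- random_match_scene()
      cands <- match_concepts(sc$expanded, index_codes(sc$repo))
      cons <- consolidate_candidates(cands)
      expect_identical(vapply(cons, function(x) x$concept_id, character(1)),
                       vapply(cands, function(x) x$concept_id, character(1)))
      expect_identical(consolidate_candidates(cons), cons)
    }
  })
})

test_that("planted fixtures are recovered with perfect precision and recall", {
  spec <- fixture_spec(seed = 5,
                       n_concepts = c(feasibility = 20, recruitment = 0,
                                      execution = 0),
                       n_shared = 0, frac_matchable = 0.6, frac_mapped = 1,
                       frac_structured = 1, frac_umls = 1)
  fix <- generate_fixture(spec)
  expect_identical(sum(fix$ground_truth$auto), 12L)
  res <- run_fixture_pipeline(fix)
  matched <- vapply(res$candidates, function(x) x$concept_id, character(1))
  planted <- fix$ground_truth$concept_id[fix$ground_truth$auto]
  expect_setequal(matched, planted)   # precision = recall = 1
  # a matchable fraction of zero leaves the matcher empty-handed
  none <- generate_fixture(fixture_spec(seed = 6,
                                        n_concepts = c(feasibility = 10,
                                                       recruitment = 0,
                                                       execution = 0),
                                        n_shared = 0, frac_matchable = 0))
  expect_length(run_fixture_pipeline(none)$candidates, 0L)
})
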