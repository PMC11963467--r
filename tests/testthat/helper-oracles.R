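# Independent brute-force oracles and small random builders used by the
# property tests. The oracles are deliberately naive (nested loops over the
# raw tables) and share no code with the implementation paths they check.

# naive reachability walk: source code -> vocabulary keys -> "Maps to"
# standard keys (plus standard source keys) -> every code on those keys
oracle_expand <- function(concept, cw) {
  ctab <- cw$concepts
  rel <- cw$relationships
  sys_out <- concept$codes$system
  code_out <- concept$codes$code
  for (i in seq_len(nrow(concept$codes))) {
    for (j in seq_len(nrow(ctab))) {
      if (ctab$system[j] != concept$codes$system[i] ||
          ctab$code[j] != concept$codes$code[i]) next
      std <- character()
      for (k in seq_len(nrow(rel))) {
        if (rel$relationship[k] == "Maps to" &&
            rel$source_key[k] == ctab$concept_key[j]) {
          std <- c(std, rel$target_key[k])
        }
      }
      if (ctab$standard[j]) std <- c(std, ctab$concept_key[j])
      for (m in seq_len(nrow(ctab))) {
        if (ctab$concept_key[m] %in% std) {
          sys_out <- c(sys_out, ctab$system[m])
          code_out <- c(code_out, ctab$code[m])
        }
      }
    }
  }
  code_tbl(sys_out, code_out)[, c("system", "code")]
}

# quadruple-nested loop: concept code x template x element x bound code,
# over normative templates only
oracle_match <- function(expanded, repo) {
  rows <- NULL
  for (ex in expanded) {
    for (t in repo$templates) {
      if (!t$normative) next
      for (el in t$elements) {
        bound <- NULL
        if (el$binding$kind == "fixed") {
          bound <- data.frame(system = el$binding$system,
                              code = el$binding$code,
                              via = "fixed", valueset_id = NA_character_,
                              valueset_date = NA_character_)
        } else if (el$binding$kind == "valueset") {
          for (v in repo$value_sets) {
            if (v$valueset_id != el$binding$valueset_id) next
            bound <- rbind(bound, data.frame(
              system = v$codes$system, code = v$codes$code, via = "valueset",
              valueset_id = v$valueset_id, valueset_date = v$effective_date))
          }
        }
        if (is.null(bound)) next
        for (b in seq_len(nrow(bound))) {
          for (i in seq_len(nrow(ex$codes))) {
            if (ex$codes$system[i] == bound$system[b] &&
                ex$codes$code[i] == bound$code[b]) {
              rows <- rbind(rows, data.frame(
                concept_id = ex$concept_id, system = bound$system[b],
                code = bound$code[b], template_id = t$template_id,
                template_date = t$effective_date,
                element_id = el$element_id, via = bound$via[b],
                valueset_id = bound$valueset_id[b],
                valueset_date = bound$valueset_date[b]))
            }
          }
        }
      }
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(concept_id = character(), system = character(),
                       code = character(), template_id = character(),
                       template_date = character(), element_id = character(),
                       via = character(), valueset_id = character(),
                       valueset_date = character())
  }
  rows <- unique(rows)
  rows[order(rows$concept_id, rows$system, rows$code, rows$template_id,
             rows$template_date, rows$element_id, rows$valueset_id,
             rows$valueset_date, method = "radix"), , drop = FALSE]
}

# flatten match_concepts() output to the oracle's row shape
candidates_as_rows <- function(candidates) {
  rows <- NULL
  for (cm in candidates) {
    occ <- as.data.frame(cm$occurrences)
    if (nrow(occ)) {
      occ <- cbind(concept_id = cm$concept_id, occ)
      rows <- rbind(rows, occ)
    }
  }
  if (is.null(rows)) return(oracle_match(list(), template_repository("x")))
  rows <- unique(rows)
  rows[order(rows$concept_id, rows$system, rows$code, rows$template_id,
             rows$template_date, rows$element_id, rows$valueset_id,
             rows$valueset_date, method = "radix"), , drop = FALSE]
}

# random small crosswalk; (system, code) pairs unique by construction
random_crosswalk <- function(n_keys = 12, n_codes = 30, n_edges = 10) {
  keys <- sprintf("K%02d", seq_len(n_keys))
  standard <- stats::runif(n_keys) < 0.45
  conc <- tibble::tibble(
    concept_key = sample(keys, n_codes, replace = TRUE),
    system = sample(c("FAKE-UMLS", "FAKE-LOINC", "FAKE-ICD10", "FAKE-ATC"),
                    n_codes, replace = TRUE),
    code = sprintf("C%03d", seq_len(n_codes)))
  conc$standard <- standard[match(conc$concept_key, keys)]
  keys <- unique(conc$concept_key)   # only keys that actually carry codes
  standard <- standard[match(keys, sprintf("K%02d", seq_len(n_keys)))]
  # mirror OMOP semantics: "Maps to" starts at non-standard source concepts
  # (standard concepts only map to themselves); targets may still be
  # non-standard so the load-time drop rule gets exercised
  nonstd <- keys[!standard]
  rel_label <- sample(c("Maps to", "Subsumes"), n_edges,
                      replace = TRUE, prob = c(0.8, 0.2))
  src_pool <- function(lab) {
    if (lab == "Maps to" && length(nonstd)) sample(nonstd, 1) else sample(keys, 1)
  }
  rel <- tibble::tibble(
    source_key = vapply(rel_label, src_pool, character(1)),
    target_key = sample(keys, n_edges, replace = TRUE),
    relationship = rel_label)
  suppressMessages(crosswalk(conc, rel))
}

# random concept with codes drawn from (and beyond) a crosswalk's pool
random_concept <- function(id, cw, extra_pool = 3) {
  pool <- rbind(cw$concepts[c("system", "code")],
                data.frame(system = "FAKE-UMLS",
                           code = sprintf("X%03d", seq_len(extra_pool))))
  k <- sample.int(4, 1) - 1L
  ix <- sample.int(nrow(pool), k)
  concept(id, codes = code_tbl(pool$system[ix], pool$code[ix]),
          group_path = sample(c("Laboratory findings", "Findings",
                                "Medication"), 1))
}

# random template repository with fixed and value-set bindings over a shared
# code pool, including non-normative decoys and multi-version value sets
random_template_repo <- function(pool, n_templates = 4, n_valuesets = 3) {
  vs <- list()
  for (v in seq_len(n_valuesets)) {
    for (d in seq_len(sample.int(2, 1))) {
      ix <- sample.int(nrow(pool), sample(2:5, 1))
      vs[[length(vs) + 1L]] <- value_set(
        sprintf("vs%02d", v), sprintf("202%d-01-01T00:00:00", d),
        code_tbl(pool$system[ix], pool$code[ix]))
    }
  }
  vs_ids <- unique(vapply(vs, function(v) v$valueset_id, character(1)))
  tpl <- list()
  for (t in seq_len(n_templates)) {
    els <- list(template_element("e0", "hl7:text", "narrative_text"))
    for (e in seq_len(sample(1:3, 1))) {
      kind <- sample(c("fixed", "valueset", "plain"), 1)
      eid <- sprintf("e%d", e)
      if (kind == "fixed") {
        ix <- sample.int(nrow(pool), 1)
        els[[length(els) + 1L]] <- template_element(
          eid, "hl7:code", "coded",
          list(kind = "fixed", system = pool$system[ix],
               code = pool$code[ix]))
      } else if (kind == "valueset") {
        els[[length(els) + 1L]] <- template_element(
          eid, "hl7:code", "coded",
          list(kind = "valueset", valueset_id = sample(vs_ids, 1)))
      } else {
        els[[length(els) + 1L]] <- template_element(
          eid, "hl7:value", sample(c("quantity", "datetime", "boolean"), 1))
      }
    }
    tpl[[length(tpl) + 1L]] <- cda_template(
      sprintf("1.2.77.%d", t), "2021-01-01T00:00:00",
      sprintf("Random template %d", t), els,
      normative = stats::runif(1) < 0.8)
  }
  template_repository("bbr-random", tpl, vs)
}

# one random end-to-end matching scene: crosswalk + concepts + templates
random_match_scene <- function(n_concepts = 8) {
  cw <- random_crosswalk()
  concepts <- lapply(sprintf("c%02d", seq_len(n_concepts)), random_concept,
                     cw = cw)
  expanded <- lapply(concepts, expand_codes, cw = cw)
  pool <- unique(rbind(cw$concepts[c("system", "code")],
                       do.call(rbind, lapply(concepts, function(co) {
                         as.data.frame(co$codes[c("system", "code")])
                       }))))
  repo <- random_template_repo(pool)
  list(cw = cw, concepts = concepts, expanded = expanded, repo = repo)
}
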