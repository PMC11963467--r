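#' @name fixtures
#' @title Synthetic fixtures with planted ground truth
#'
#' @description
#' The fixture generator builds a complete synthetic study setting: a
#' trial-concept repository, a template building-block repository, a
#' vocabulary crosswalk, and a set of hand-authored ("manual") template
#' associations, together with a ground-truth table stating exactly which
#' concepts must be matched automatically and what each concept's final
#' mapping status is. All synthetic codes use reserved fake code systems
#' (`FAKE-UMLS`, `FAKE-LOINC`, `FAKE-SNOMED`, `FAKE-ICD10`) so fixtures can
#' never be mistaken for licensed vocabulary content. Generation is fully
#' deterministic given the seed.
#'
#' [elga_preset()] returns a specification whose planted per-group mapping
#' statuses reproduce the count structure of a nation-wide CDA-based EHR
#' system analysis: use-case datasets of 75/149/133 concepts, 308 of the 357
#' per-use-case concept slots carrying UMLS-type codes, 75 concepts (85
#' source codes) automatically matchable, and per-group structured/free-text
#' splits whose per-use-case totals are 71/67, 135/119 and 109/89.
NULL

#' Specify a synthetic fixture
#'
#' @param seed integer seed; all randomness of the generator derives from it
#' @param n_concepts named integer vector: total concepts per use-case
#'   dataset (including inherited shared concepts)
#' @param n_shared number of concepts placed in a shared "basic" dataset and
#'   inherited by the feasibility and recruitment datasets
#' @param frac_umls fraction of concepts carrying UMLS-type codes
#' @param frac_matchable fraction of concepts automatically matchable via
#'   the crosswalk (these are always structured-mapped and coded)
#' @param frac_mapped fraction of concepts mapped to at least one template
#'   element
#' @param frac_structured fraction of mapped concepts whose target is
#'   structured rather than free-text
#' @param group_weights named numeric sampling weights for concept groups
#' @param n_generic_templates number of generic (code+value) observation
#'   templates per use case over which matchable concepts are spread
#' @param plan optional prebuilt plan table (one row per concept); used by
#'   [elga_preset()] to pin exact per-group statuses
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L,
                         n_concepts = c(feasibility = 75, recruitment = 149,
                                        execution = 133),
                         n_shared = 8L,
                         frac_umls = 0.86,
                         frac_matchable = 0.21,
                         frac_mapped = 0.88,
                         frac_structured = 0.873,
                         group_weights = NULL,
                         n_generic_templates = 1L,
                         plan = NULL) {
  fr <- c(frac_umls = frac_umls, frac_matchable = frac_matchable,
          frac_mapped = frac_mapped, frac_structured = frac_structured)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (any(n_concepts < 0) || n_shared < 0 || n_generic_templates < 1) {
    abort("counts must be non-negative (and >= 1 generic template)")
  }
  if (is.null(plan)) {
    if (frac_matchable > frac_umls) {
      abort("infeasible spec: matchable fraction exceeds coded (UMLS) fraction")
    }
    if (frac_matchable > frac_mapped * frac_structured) {
      abort("infeasible spec: matchable fraction exceeds structured-mapped fraction")
    }
    missing_uc <- setdiff(c("feasibility", "recruitment", "execution"),
                          names(n_concepts))
    n_concepts[missing_uc] <- 0L
    if (n_shared > 0 &&
        min(n_concepts[c("feasibility", "recruitment")]) < n_shared) {
      abort("infeasible spec: shared concepts need room in feasibility and recruitment")
    }
  }
  if (is.null(group_weights)) {
    group_weights <- c("Laboratory findings" = 0.45, "Findings" = 0.12,
                       "Medication" = 0.08, "Medical history" = 0.08,
                       "Demographics" = 0.06, "Diagnosis" = 0.06,
                       "Procedure" = 0.05, "Scores & classification" = 0.05,
                       "Substance use" = 0.05)
  }
  structure(list(seed = as.integer(seed), n_concepts = n_concepts,
                 n_shared = as.integer(n_shared), frac_umls = frac_umls,
                 frac_matchable = frac_matchable, frac_mapped = frac_mapped,
                 frac_structured = frac_structured,
                 group_weights = group_weights,
                 n_generic_templates = as.integer(n_generic_templates),
                 plan = plan),
            class = "fixture_spec")
}

# data types by concept group (cosmetic realism in generated repositories)
group_data_type <- function(group) {
  quantity <- c("Laboratory findings", "Laboratory", "Lab data", "Vital signs")
  coded <- c("Diagnosis", "Procedure", "Medication", "Concomitant medication",
             "Demographics", "Medical device", "Adverse events")
  count <- c("Scores & classification")
  ifelse(group %in% quantity, "Quantity",
         ifelse(group %in% coded, "Code",
                ifelse(group %in% count, "Count", "Text")))
}

# one plan row per concept
plan_row <- function(concept_id, home, inherit_to, group, status, auto,
                     has_umls, n_match_codes, extra_free_text) {
  tibble(concept_id = concept_id, home = home, inherit_to = inherit_to,
         group = group, status = status, auto = auto, has_umls = has_umls,
         n_match_codes = as.integer(n_match_codes),
         extra_free_text = extra_free_text)
}

# internal: random plan under the spec's fractions (RNG already seeded)
build_random_plan <- function(spec) {
  ucs <- c("feasibility", "recruitment", "execution")
  n <- spec$n_concepts[ucs]
  rows <- list()

  shared <- NULL
  if (spec$n_shared > 0L) {
    p_struct <- spec$frac_mapped * spec$frac_structured
    p_free <- spec$frac_mapped * (1 - spec$frac_structured)
    status <- sample(c("structured", "free_text", "unmapped"), spec$n_shared,
                     replace = TRUE, prob = c(p_struct, p_free, 1 - p_struct - p_free))
    shared <- plan_row(
      sprintf("B%03d", seq_len(spec$n_shared)), "basic",
      "feasibility,recruitment",
      sample(names(spec$group_weights), spec$n_shared, replace = TRUE,
             prob = spec$group_weights),
      status, auto = FALSE,
      has_umls = stats::runif(spec$n_shared) < spec$frac_umls,
      n_match_codes = 0L, extra_free_text = FALSE)
    rows[["basic"]] <- shared
  }

  for (uc in ucs) {
    n_uc <- n[[uc]]
    sh_here <- if (!is.null(shared) && uc %in% c("feasibility", "recruitment")) {
      shared
    } else NULL
    n_local <- n_uc - if (is.null(sh_here)) 0L else nrow(sh_here)
    if (n_local <= 0L) next
    q_map <- round_half_up(spec$frac_mapped * n_uc)
    q_str <- round_half_up(spec$frac_structured * q_map)
    q_auto <- round_half_up(spec$frac_matchable * n_uc)
    q_umls <- round_half_up(spec$frac_umls * n_uc)
    if (!is.null(sh_here)) {
      q_map <- q_map - sum(sh_here$status != "unmapped")
      q_str <- q_str - sum(sh_here$status == "structured")
      q_umls <- q_umls - sum(sh_here$has_umls)
    }
    lm <- max(0L, min(n_local, q_map))
    ls <- max(0L, min(lm, q_str))
    la <- max(0L, min(ls, q_auto))
    lu <- max(la, min(n_local, max(0L, q_umls)))
    status <- sample(c(rep("structured", ls), rep("free_text", lm - ls),
                       rep("unmapped", n_local - lm)))
    auto <- rep(FALSE, n_local)
    str_ix <- which(status == "structured")
    auto[str_ix[sample.int(length(str_ix), la)]] <- TRUE
    umls <- auto
    extra <- max(0L, lu - sum(umls))
    if (extra > 0L) {
      off_ix <- which(!umls)
      umls[off_ix[sample.int(length(off_ix), extra)]] <- TRUE
    }
    rows[[uc]] <- plan_row(
      sprintf("%s%03d", toupper(substr(uc, 1, 1)), seq_len(n_local)),
      uc, "",
      sample(names(spec$group_weights), n_local, replace = TRUE,
             prob = spec$group_weights),
      status, auto, umls,
      n_match_codes = ifelse(auto, ifelse(stats::runif(n_local) < 0.125, 2L, 1L), 0L),
      extra_free_text = status == "structured" & !auto &
        seq_len(n_local) %% 4L == 0L)
  }
  bind_rows(rows)
}

# planted per-group mapping counts of the ELGA-like preset
elga_group_table <- function() {
  tribble_ <- function(...) {
    m <- matrix(list(...), ncol = 5, byrow = TRUE)
    tibble(use_case = unlist(m[, 1]), group = unlist(m[, 2]),
           n = as.integer(unlist(m[, 3])),
           mapped = as.integer(unlist(m[, 4])),
           structured = as.integer(unlist(m[, 5])))
  }
  tribble_(
    "feasibility", "Demographics",             5,  5,  5,
    "feasibility", "Medical history",          8,  7,  4,
    "feasibility", "Diagnosis",                4,  3,  3,
    "feasibility", "Procedure",                3,  1,  0,
    "feasibility", "Findings",                 7,  7,  7,
    "feasibility", "Laboratory findings",     41, 41, 41,
    "feasibility", "Medication",               7,  7,  7,
    "recruitment", "Demographics",             5,  5,  5,
    "recruitment", "Medical history",         10,  7,  4,
    "recruitment", "Medical device",           1,  1,  0,
    "recruitment", "Diagnosis",                5,  4,  4,
    "recruitment", "Procedure",                3,  1,  0,
    "recruitment", "Findings",                25, 18, 16,
    "recruitment", "Laboratory findings",     81, 81, 81,
    "recruitment", "Medication",               9,  8,  8,
    "recruitment", "Scores & classification",  9,  9,  0,
    "recruitment", "Patient characteristics",  1,  1,  1,
    "execution",   "Demographics",             4,  2,  2,
    "execution",   "ECG",                      9,  0,  0,
    "execution",   "Adverse events",          11,  5,  5,
    "execution",   "Medical history",          4,  4,  1,
    "execution",   "Disease characteristics",  2,  2,  2,
    "execution",   "Disposition",              2,  0,  0,
    "execution",   "Patient reported outcome", 3,  2,  0,
    "execution",   "Vital signs",              8,  8,  7,
    "execution",   "Laboratory",              57, 57, 57,
    "execution",   "Lab data",                 6,  6,  4,
    "execution",   "Concomitant medication",   9,  8,  8,
    "execution",   "Surgery",                  5,  4,  0,
    "execution",   "Substance use",            8,  8,  0,
    "execution",   "Tumor resp.",              5,  3,  3
  )
}

#' Fixture specification reproducing the reference study's count structure
#'
#' Builds a fully pinned plan: use-case datasets of 75, 149, and 133
#' concepts; the demographics and procedure groups of the feasibility and
#' recruitment datasets realized as 8 shared "basic" concepts pulled in by
#' inheritance; per-group mapping statuses planted so the analyzer yields
#' per-use-case rows (75, 71, 67), (149, 135, 119), (133, 109, 89) and the
#' overall row (357, 315, 275); 75 automatically matchable lab concepts, 10
#' of which carry a second matching source code (85 matchable source codes
#' in total); 308 of the 357 per-use-case concept slots UMLS-coded.
#'
#' @param seed integer seed forwarded to the generator
#' @return a [fixture_spec()] with a prebuilt plan
#' @export
elga_preset <- function(seed = 1L) {
  tab <- elga_group_table()
  rows <- list()
  bi <- 0L
  counters <- c(feasibility = 0L, recruitment = 0L, execution = 0L)

  shared_groups <- c("Demographics", "Procedure")
  # shared basic concepts (identical planted rows in feasibility and
  # recruitment, so one status per concept id is consistent with both)
  for (g in shared_groups) {
    r <- tab[tab$use_case == "feasibility" & tab$group == g, ]
    status <- c(rep("structured", r$structured),
                rep("free_text", r$mapped - r$structured),
                rep("unmapped", r$n - r$mapped))
    ids <- sprintf("B%03d", bi + seq_len(r$n))
    bi <- bi + r$n
    rows[[paste0("basic-", g)]] <- plan_row(
      ids, "basic", "feasibility,recruitment", g, status, auto = FALSE,
      has_umls = status != "unmapped", n_match_codes = 0L,
      extra_free_text = FALSE)
  }

  auto_quota <- c(feasibility = 20L, recruitment = 30L, execution = 25L)
  lab_group <- c(feasibility = "Laboratory findings",
                 recruitment = "Laboratory findings",
                 execution = "Laboratory")
  for (i in seq_len(nrow(tab))) {
    uc <- tab$use_case[i]
    g <- tab$group[i]
    if (uc %in% c("feasibility", "recruitment") && g %in% shared_groups) next
    status <- c(rep("structured", tab$structured[i]),
                rep("free_text", tab$mapped[i] - tab$structured[i]),
                rep("unmapped", tab$n[i] - tab$mapped[i]))
    k <- tab$n[i]
    ids <- sprintf("%s%03d", toupper(substr(uc, 1, 1)),
                   counters[[uc]] + seq_len(k))
    counters[[uc]] <- counters[[uc]] + k
    auto <- rep(FALSE, k)
    if (g == lab_group[[uc]]) auto[seq_len(auto_quota[[uc]])] <- TRUE
    has_umls <- status != "unmapped"
    if (uc == "execution" && g == "Substance use") {
      # seven free-text lab-style lifestyle concepts lack UMLS codes, fixing
      # the repository-wide coded fraction at 308 of 357 slots
      has_umls[seq_len(7)] <- FALSE
    }
    n_match <- ifelse(auto, 1L, 0L)
    if (uc == "feasibility" && g == lab_group[["feasibility"]]) {
      n_match[seq_len(10)] <- 2L  # 85 matchable source codes over 75 concepts
    }
    rows[[paste(uc, g)]] <- plan_row(
      ids, uc, "", g, status, auto, has_umls, n_match,
      extra_free_text = status == "structured" & !auto &
        seq_len(k) %% 4L == 0L)
  }
  fixture_spec(seed = seed,
               n_concepts = c(feasibility = 75, recruitment = 149,
                              execution = 133),
               n_shared = 8L, plan = bind_rows(rows))
}

#' Generate a synthetic fixture
#'
#' Deterministic given `spec$seed`: the same spec yields byte-identical
#' serialized files.
#'
#' @param spec a [fixture_spec()]
#' @return object of class `trial_fixture`: a list with elements `concepts`
#'   (a [concept_repository()]), `templates` (a [template_repository()]),
#'   `crosswalk` (a [crosswalk()]), `manual_associations` (an
#'   [association_document()]), and `ground_truth` (a tibble with one row
#'   per use-case concept slot: `concept_id`, `use_case`, `dataset_id`,
#'   `group`, `status`, `auto`, `has_umls`, `n_match_codes`)
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  plan <- spec$plan %||% build_random_plan(spec)
  plan <- plan[order(plan$concept_id, method = "radix"), , drop = FALSE]
  ucs <- c("feasibility", "recruitment", "execution")

  # --- terminology codes --------------------------------------------------
  plan$umls_codes <- vector("list", nrow(plan))
  plan$match_codes <- vector("list", nrow(plan))
  cu <- 0L
  for (i in seq_len(nrow(plan))) {
    if (!plan$has_umls[i]) next
    k <- max(1L, plan$n_match_codes[i])
    codes <- sprintf("CU%04d", cu + seq_len(k))
    cu <- cu + k
    plan$umls_codes[[i]] <- codes
    if (plan$auto[i]) plan$match_codes[[i]] <- codes[seq_len(plan$n_match_codes[i])]
  }
  snomed_at <- which(plan$has_umls)[seq_along(which(plan$has_umls)) %% 7L == 0L]

  # --- crosswalk ----------------------------------------------------------
  cw_c <- list()
  cw_r <- list()
  add_mapping <- function(umls_code, std_code, synonym_icd = NULL) {
    src_key <- paste0("K-", umls_code)
    std_key <- paste0("STD-", umls_code)
    cw_c[[length(cw_c) + 1L]] <<- tibble(
      concept_key = c(src_key, std_key),
      system = c("FAKE-UMLS", "FAKE-LOINC"),
      code = c(umls_code, std_code),
      standard = c(FALSE, TRUE))
    if (!is.null(synonym_icd)) {
      cw_c[[length(cw_c) + 1L]] <<- tibble(
        concept_key = std_key, system = "FAKE-ICD10", code = synonym_icd,
        standard = TRUE)
    }
    cw_r[[length(cw_r) + 1L]] <<- tibble(
      source_key = src_key, target_key = std_key, relationship = "Maps to")
  }
  n_auto_code <- 0L
  nonauto_coded <- 0L
  for (i in seq_len(nrow(plan))) {
    if (plan$auto[i]) {
      for (code in plan$match_codes[[i]]) {
        n_auto_code <- n_auto_code + 1L
        syn <- if (n_auto_code %% 3L == 0L) sub("^CU", "I", code) else NULL
        add_mapping(code, sub("^CU", "L", code), syn)
      }
    } else if (plan$has_umls[i]) {
      nonauto_coded <- nonauto_coded + 1L
      if (nonauto_coded %% 3L == 0L) {
        # decoy mapping: expands to a standard code absent from every template
        code <- plan$umls_codes[[i]][1]
        add_mapping(code, sub("^CU", "LX", code))
      }
    }
  }
  cw <- crosswalk(
    if (length(cw_c)) bind_rows(cw_c) else {
      tibble(concept_key = character(), system = character(),
             code = character(), standard = logical())
    },
    if (length(cw_r)) bind_rows(cw_r) else {
      tibble(source_key = character(), target_key = character(),
             relationship = character())
    })

  # --- templates ----------------------------------------------------------
  templates <- list()
  value_sets <- list()
  for (u in seq_along(ucs)) {
    uc <- ucs[u]
    in_uc <- plan$home == uc |
      vapply(strsplit(plan$inherit_to, ","), function(x) uc %in% x, logical(1))
    loinc <- sub("^CU", "L", unlist(plan$match_codes[plan$auto & in_uc]))
    n_gen <- spec$n_generic_templates
    if (length(loinc)) {
      chunks <- split(sort(loinc), rep(seq_len(n_gen), length.out = length(loinc)))
      for (j in seq_along(chunks)) {
        vs_id <- sprintf("vs-lab-%s-%d", uc, j)
        full <- code_tbl(rep("FAKE-LOINC", length(chunks[[j]])), chunks[[j]])
        value_sets[[length(value_sets) + 1L]] <-
          value_set(vs_id, "2021-06-01T00:00:00", full)
        half <- full[seq_len(ceiling(nrow(full) / 2)), , drop = FALSE]
        value_sets[[length(value_sets) + 1L]] <-
          value_set(vs_id, "2020-06-01T00:00:00", half)
        templates[[length(templates) + 1L]] <- cda_template(
          sprintf("1.2.99.%d.1%d", u, j), "2021-01-01T00:00:00",
          sprintf("Laboratory Observation %d (%s)", j, uc),
          list(template_element("e-code", "hl7:code", "coded",
                                list(kind = "valueset", valueset_id = vs_id)),
               template_element("e-value", "hl7:value", "quantity"),
               template_element("e-text", "hl7:text", "narrative_text")))
      }
      # draft twin of the first lab template: must be ignored by the matcher
      templates[[length(templates) + 1L]] <- cda_template(
        sprintf("1.2.99.%d.40", u), "2021-01-01T00:00:00",
        sprintf("Draft Laboratory Observation (%s)", uc),
        list(template_element("e-code", "hl7:code", "coded",
                              list(kind = "valueset",
                                   valueset_id = sprintf("vs-lab-%s-1", uc))),
             template_element("e-value", "hl7:value", "quantity")),
        normative = FALSE)
    }
    if (!any(in_uc)) next
    templates[[length(templates) + 1L]] <- cda_template(
      sprintf("1.2.99.%d.20", u), "2021-01-01T00:00:00",
      sprintf("Clinical Entry (%s)", uc),
      list(template_element("e-val", "hl7:value", "quantity"),
           template_element("e-time", "hl7:effectiveTime", "datetime")))
    templates[[length(templates) + 1L]] <- cda_template(
      sprintf("1.2.99.%d.30", u), "2021-01-01T00:00:00",
      sprintf("Lifestyle - uncoded (%s)", uc),
      list(template_element("e-text", "hl7:text", "narrative_text")))
  }
  bbr <- template_repository("bbr-synthetic", templates, value_sets)

  # --- concept repository -------------------------------------------------
  make_concept <- function(i) {
    codes <- code_tbl()
    if (plan$has_umls[i]) {
      sys <- rep("FAKE-UMLS", length(plan$umls_codes[[i]]))
      cds <- plan$umls_codes[[i]]
      if (i %in% snomed_at) {
        sys <- c(sys, "FAKE-SNOMED")
        cds <- c(cds, sub("^CU", "S", cds[1]))
      }
      codes <- code_tbl(sys, cds)
    }
    concept(plan$concept_id[i],
            name = sprintf("%s %s", plan$group[i], plan$concept_id[i]),
            data_type = group_data_type(plan$group[i]),
            codes = codes, group_path = plan$group[i],
            description = sprintf("Synthetic %s element", tolower(plan$group[i])))
  }
  datasets <- list()
  basic_rows <- which(plan$home == "basic")
  if (length(basic_rows)) {
    datasets[["ds-basic"]] <- concept_dataset(
      "ds-basic", "Basic data elements", "basic",
      lapply(basic_rows, make_concept))
  }
  for (uc in ucs) {
    locals <- which(plan$home == uc)
    inherited <- which(vapply(strsplit(plan$inherit_to, ","),
                              function(x) uc %in% x, logical(1)))
    if (!length(locals) && !length(inherited)) next
    concepts <- c(
      lapply(locals, make_concept),
      lapply(inherited, function(i) {
        concept(plan$concept_id[i],
                origin = list(dataset = "ds-basic",
                              concept = plan$concept_id[i]))
      }))
    datasets[[paste0("ds-", uc)]] <- concept_dataset(
      paste0("ds-", uc), paste("Use case", uc), uc, concepts)
  }
  repo <- concept_repository("synthetic-inventory", datasets)

  # --- manual associations ------------------------------------------------
  first_uc <- function(i) {
    if (plan$home[i] != "basic") return(plan$home[i])
    strsplit(plan$inherit_to[i], ",")[[1]][1]
  }
  manual <- list()
  for (i in seq_len(nrow(plan))) {
    if (plan$auto[i] || plan$status[i] == "unmapped") next
    u <- match(first_uc(i), ucs)
    if (plan$status[i] == "structured") {
      manual[[length(manual) + 1L]] <- template_association(
        plan$concept_id[i], sprintf("1.2.99.%d.20", u),
        "2021-01-01T00:00:00", "e-val", provenance = "manual")
    }
    if (plan$status[i] == "free_text" || plan$extra_free_text[i]) {
      manual[[length(manual) + 1L]] <- template_association(
        plan$concept_id[i], sprintf("1.2.99.%d.30", u),
        "2021-01-01T00:00:00", "e-text", provenance = "manual")
    }
  }
  manual_doc <- association_document("synthetic-manual-mappings", manual)

  # --- ground truth -------------------------------------------------------
  gt <- list()
  status_name <- c(unmapped = "unmapped", free_text = "mapped_free_text",
                   structured = "mapped_structured")
  for (uc in ucs) {
    in_uc <- plan$home == uc |
      vapply(strsplit(plan$inherit_to, ","), function(x) uc %in% x, logical(1))
    if (!any(in_uc)) next
    sub <- plan[in_uc, , drop = FALSE]
    gt[[uc]] <- tibble(concept_id = sub$concept_id, use_case = uc,
                       dataset_id = paste0("ds-", uc), group = sub$group,
                       status = unname(status_name[sub$status]),
                       auto = sub$auto, has_umls = sub$has_umls,
                       n_match_codes = sub$n_match_codes)
  }
  ground_truth <- bind_rows(gt)

  structure(list(spec = spec, concepts = repo, templates = bbr,
                 crosswalk = cw, manual_associations = manual_doc,
                 ground_truth = ground_truth),
            class = "trial_fixture")
}

#' Write a fixture to disk
#'
#' Serializes the four pipeline inputs (concept repository XML, template
#' repository XML, crosswalk CSVs), the manual association document, and the
#' ground-truth table (JSON).
#'
#' @param fixture a [generate_fixture()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "trial_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    concepts = file.path(dir, "concepts.xml"),
    templates = file.path(dir, "templates.xml"),
    crosswalk_concepts = file.path(dir, "crosswalk_concepts.csv"),
    crosswalk_relationships = file.path(dir, "crosswalk_relationships.csv"),
    manual_associations = file.path(dir, "manual_associations.xml"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  writeLines(write_concept_repository(fixture$concepts), paths["concepts"],
             useBytes = TRUE)
  writeLines(write_template_repository(fixture$templates), paths["templates"],
             useBytes = TRUE)
  utils::write.csv(fixture$crosswalk$concepts, paths["crosswalk_concepts"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fixture$crosswalk$relationships,
                   paths["crosswalk_relationships"], row.names = FALSE,
                   quote = FALSE)
  writeLines(write_associations(fixture$manual_associations),
             paths["manual_associations"], useBytes = TRUE)
  jsonlite::write_json(fixture$ground_truth, paths["ground_truth"],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full automatic-matching pipeline on a fixture
#'
#' Convenience wrapper used by the command-line interface and the examples:
#' expands every concept's codes, matches them against the template index,
#' consolidates, accepts all candidates (the fixture's planted matches are
#' exact, so validation cannot reject anything), converts them to automatic
#' associations, pools the manual associations, and analyzes coverage.
#'
#' @param fixture a [generate_fixture()] result
#' @return list with `expanded`, `candidates`, `auto_associations`, and
#'   `report` (a [coverage_report()])
#' @export
run_fixture_pipeline <- function(fixture) {
  repo <- resolve_inheritance(fixture$concepts)
  all_concepts <- list()
  for (ds in repo$datasets) {
    for (co in ds$concepts) all_concepts[[co$id]] <- co
  }
  expanded <- map(all_concepts, expand_codes, cw = fixture$crosswalk)
  idx <- index_codes(fixture$templates)
  cands <- consolidate_candidates(match_concepts(expanded, idx))
  cands <- set_candidate_status(cands, "accepted")
  auto <- to_associations(cands, fixture$templates)
  report <- analyze_coverage(fixture$concepts,
                             list(auto, fixture$manual_associations),
                             fixture$templates)
  list(expanded = expanded, candidates = cands, auto_associations = auto,
       report = report)
}
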