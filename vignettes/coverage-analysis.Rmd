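---
title: "Analyzing trial data-element coverage of CDA-based shared EHR systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing trial data-element coverage of CDA-based shared EHR systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcover)
```

## The question

Shared (often nation-wide) electronic health record systems integrate
documents from all of a patient's care providers under one standardized
information model, typically HL7 CDA. That makes them attractive secondary
data sources for clinical trials — *if* they can actually hold the data
elements trials need. This package implements a systematic way to answer
that question for any CDA-based system whose templates are available in
machine-readable form:

1. consolidate the trial-relevant data elements into a formal concept
   repository (use-case datasets for feasibility checking, patient
   identification/recruitment, and trial execution, with shared elements in
   a "basic" dataset pulled in by inheritance);
2. expand each concept's terminology codes across code systems through an
   OMOP-style crosswalk and scan the EHR system's CDA templates for exact
   code matches;
3. validate candidates, add manual mappings for templates without
   terminology annotations, and store everything as formal template
   associations;
4. analyze the associations into coverage statistics — per use case, per
   concept group, and overall, distinguishing structured from free-text
   targets.

The analysis is *structural*: it states what the EHR system allows to be
recorded, not what clinicians actually fill in. Data availability and
completeness are explicitly out of scope.

## The coverage statistic

For a scope $S$ (a use case, a concept group, or everything) with $n$
concepts, of which $m$ are mapped to at least one template element and $s$
are mapped to at least one *structured* element, the report prints
$n$, $m$ ($\lfloor 100m/n + 0.5 \rfloor\%$), and $s$
($\lfloor 100s/n + 0.5 \rfloor\%$).

Two counting rules matter:

* **Structured precedence.** A concept mapped simultaneously to a
  structured and a free-text element counts as structured. An element is
  structured unless its content kind is narrative text; coded, quantity,
  date-time and boolean content all count as structured.
* **Per-use-case counting.** A concept shared between use cases (inherited
  from the basic dataset) is counted once in *each* use case, so the
  overall row is the sum of the use-case rows. Classification is keyed by
  concept id, so the shared concept's status is identical wherever it
  appears.

Percentages use half-up rounding to integer percent (`round_half_up()`);
this is the only rounding rule consistent with every published table cell
we checked, e.g. $67/75 \to 89\%$ and $119/149 \to 80\%$.

## Code expansion and exact matching

Concept repositories mostly carry UMLS concept identifiers; template
bindings use LOINC, ICD-10, ATC and friends. The crosswalk bridges them with
the OMOP vocabulary's standard-concept semantics: every (system, code) pair
belongs to a vocabulary concept key, `"Maps to"` links source keys to
standard keys, and two codes are equivalent iff they reach a shared
standard key. `expand_codes()` therefore:

* follows `"Maps to"` exactly **one hop** (no transitive closure — this is
  deliberate and mirrors how the OMOP tables are meant to be read; standard
  concepts map to themselves, not onward);
* fans out to every code attached to the reached standard keys;
* lets source codes absent from the crosswalk contribute only themselves;
* expands **all** source codes uniformly — UMLS and SNOMED CT alike. The
  workflow this models left that point open; uniform expansion is the
  simpler and stricter-to-test choice, and concepts whose extra codes find
  no crosswalk entry lose nothing by it.

Matching (`match_concepts()` over `index_codes()`) is **exact** on the
canonical (system, code) pair after OID-to-short-name normalization.
Display names are never compared: lexical matching of labels is a known
source of silent mismatches, and the workflow places everything
code-equality cannot decide into the manual validation step (represented
here as candidate status edits and hand-authored association documents).
Codes are collected from fixed bindings and from value-set bindings of a
template's direct elements; nested template references are not followed.

Consolidation collapses duplicate hits from multiple versions of one value
set onto the lexicographically latest effective date and groups codes
hitting the same (template, element, value set) into one occurrence. A
match on a *generic* template — a coded element with a value-set binding
next to a non-narrative `value` sibling, like a generic lab observation
specialized by its LOINC code — converts into a paired association spanning
both elements, carrying the matched code as qualifier.

Only templates referenced by a document type of normative status take part
in indexing, and the analyzer warns about (and ignores) associations
pointing at non-normative templates: a draft template is not a place data
can actually live.

## Data-type normalization

Source inventories describe elements with form-oriented labels (`Float`,
`Integer`, `Text`, `String`, `Date`, `Boolean`). `normalize_data_type()`
refines them using a semantic hint derived from the concept's group
(laboratory findings and vital signs → quantity; diagnosis, procedure and
demographic code fields → code; counts → count):

| hint | source labels | result |
|---|---|---|
| quantity | Float, Integer, Text | `Quantity` |
| code | String, Text, Integer | `Code` |
| count | Integer, Float | `Count` |

Without an applicable hint the label maps by identity into the enumeration.
`Float` and `Integer` have no identity image there, so they default to
`Quantity` and `Count` respectively, and `String` folds into `Text` — the
least-surprising reading for numeric and string form fields. Known
erroneous source labels (a date-typed diagnosis code and the like) are
treated as fixture data corrected at authoring time, not inferred.

## The synthetic fixture generator

No licensed vocabulary content and no real template repository ships with
the package; `generate_fixture()` builds the whole study setting
synthetically, with planted ground truth, under reserved fake code systems
(`FAKE-UMLS`, `FAKE-LOINC`, …). All randomness derives from the single
integer seed, and serialization is canonical, so the same spec yields
byte-identical files.

`fixture_spec()` defaults encode the reference study's conditions: datasets
of 75/149/133 concepts, 8 shared basic concepts, 86% of concepts
UMLS-coded, 21% automatically matchable, 88% mapped, 87.3% of mapped
concepts structured. `elga_preset()` goes further and pins a complete plan:
every published group row is planted verbatim (all lab concepts structured
and the source of the automatic matches, procedures 1-of-3 mapped with no
structured target, nine ECG concepts unmapped, and so on), the shared basic
dataset is realized as the demographics and procedure groups common to the
feasibility and recruitment datasets (their published rows coincide, as
they must for a per-concept status), and ten of the 75 matchable concepts
carry a second matching source code so that 85 matchable codes consolidate
onto 75 concepts. All group rows were checked to be arithmetically
consistent with the use-case totals before being encoded; none needed
adjustment.

Each generated scene also contains adversarial material the pipeline must
get right: two versions of each lab value set (version deduplication), a
non-normative "draft" twin of the lab template binding the same value set
(normative filtering), decoy crosswalk mappings onto standard codes that
occur in no template (expansion without matches), extra free-text
associations on some structured concepts (structured precedence), and
SNOMED-style codes outside the crosswalk (self-contribution only).

What the fixtures do **not** emulate: real template nesting and datatype
flavors, real terminology semantics (fake codes are equivalent only by
construction), label noise, and the human judgment inside manual mapping.
Passing tests therefore demonstrate that the machinery — parsing,
expansion, matching, consolidation, classification, counting, rounding,
serialization — is correct, not that any particular real EHR system has
any particular coverage.

## Numerical and degenerate-input choices

* Effective dates are ISO-8601 strings compared lexicographically; the
  "latest" value-set version is the lexicographic maximum (distinct
  versions cannot share a date, since (id, date) is unique per repository).
* Code sets are canonical tibbles sorted by (system, code); sibling order
  in XML files never matters.
* Empty datasets parse with a warning; concepts without codes expand to the
  empty set and simply never match; a zero denominator yields 0%.
* Candidate status moves only pending → accepted/rejected; converting
  pending candidates to associations is an error, so no unvalidated match
  can slip into a report.
* YAML output has a fixed, sorted key schema
  (`inst/schema/coverage-report.schema.json`) and is byte-stable across
  runs.

## Problem sizes used in the test suite

The property suites run on deliberately small randomized scenes: 200
random matching scenes of up to ~12 concepts and a handful of templates are
compared against a brute-force quadruple-loop oracle; 40 random crosswalks
against a naive reachability oracle; ten random full fixtures (4–20
concepts per use case) through the complete pipeline against their planted
ground truth; plus the full 357-concept preset end to end. Small scenes
keep each oracle comparison exhaustive and the whole suite fast while
covering the combinatorics (fixed vs value-set bindings, version
multiplicity, non-normative templates, shared concepts) far more densely
than one large fixture would.

## Limitations

* Coverage is structural; actual documentation practice can only lower the
  usable fraction, and this package by design says nothing about it.
* Exact-code matching finds only what terminology annotations expose;
  everything else is manual work, which the package stores and counts but
  cannot perform.
* The DECOR dialect read and written here is a documented subset of the
  full DECOR schema; real exports restricted to these elements parse, but
  full schema compatibility is not claimed.
* Value-set and fixed-code scanning covers a template's direct elements;
  codes reachable only through nested template references are invisible to
  the matcher and must be mapped manually.
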