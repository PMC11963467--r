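# trialcover

Can a shared electronic health record (EHR) system — a nation-wide,
HL7 CDA based system integrating documents from all of a patient's care
providers — actually hold the data elements that clinical trials need?
`trialcover` implements a systematic, reproducible way to answer that for
researchers in clinical research informatics: it models a trial-concept
repository (use-case datasets for trial **feasibility checking**, **patient
identification/recruitment**, and **trial execution**, with shared elements
inherited from a basic dataset), expands each concept's terminology codes
across code systems through an OMOP-style `"Maps to"` crosswalk, scans the
EHR system's CDA templates for exact code matches, stores validated
mappings as formal template associations, and reports coverage statistics.

For a scope with *n* concepts, *m* of them mapped to at least one template
element and *s* to at least one structured (non-narrative) element, the
report prints *n*, *m* (⌊100·m/n + ½⌋%), and *s* (⌊100·s/n + ½⌋%). A
concept mapped to structured and free-text targets simultaneously counts as
structured; a concept shared between use cases counts once per use case, so
the overall row is the sum of the use-case rows. The analysis is
structural — what the system *allows* to be recorded — and deliberately
says nothing about actual data availability.

Everything ships with a synthetic fixture generator (reserved `FAKE-*` code
systems, planted ground truth, fully seed-deterministic), including a
preset that reproduces the count structure of a published analysis of a
nation-wide EHR system.

## Worked example

```r
library(trialcover)

fix <- generate_fixture(elga_preset())   # synthetic study setting
res <- run_fixture_pipeline(fix)         # expand -> match -> consolidate ->
                                         # accept -> associate -> analyze
print(res$report)
#> <coverage_report>
#>                                 n  mapped      structured
#> feasibility                    75    71 (95%)    67 (89%)
#> recruitment                   149   135 (91%)   119 (80%)
#> execution                     133   109 (82%)    89 (67%)
#> Overall                       357   315 (88%)   275 (77%)

repository_summary(fix$concepts)$umls_coded_pct
#> [1] 86

hits <- source_code_hits(res$candidates, res$expanded)
nrow(hits); length(res$candidates)
#> [1] 85
#> [1] 75
```

Reading the output: of the 357 use-case concept slots, 315 (88%) can be
recorded in the synthetic EHR system at all and 275 (77%) in structured
form; feasibility checking has the best coverage (95%/89%). 86% of the
concepts carry UMLS-type codes, and the automatic code-based matcher alone
resolves 85 source codes onto 75 concepts — 21% of the slots — before
manual mapping fills in the rest. `write_report_yaml(res$report)` emits the
deterministic YAML report (schema in
`inst/schema/coverage-report.schema.json`).

The same workflow runs from the shell against files:

```sh
inst/exec/trialcover fixtures --preset elga --seed 1 --out-dir work/
inst/exec/trialcover match   --concepts work/concepts.xml --bbr work/templates.xml \
    --crosswalk-concepts work/crosswalk_concepts.csv \
    --crosswalk-rels work/crosswalk_relationships.csv \
    --out work/auto.xml --candidates-out work/review.csv
inst/exec/trialcover analyze --concepts work/concepts.xml \
    --assoc work/auto.xml --assoc work/manual_associations.xml \
    --bbr work/templates.xml --out work/report.yaml
```

To analyze a real system, point `--concepts`/`--bbr` at DECOR-dialect XML
exports (the supported subset is documented in `?decor_io`) and supply a
real crosswalk as the two CSV tables (`concept_key,system,code,standard`
and `source_key,target_key,relationship`).

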