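---
title: "FAIR maturity assessment of COMBINE models and archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAIR maturity assessment of COMBINE models and archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faircombine)
```

## The assessment model

A FAIR assessment scores a resource against a list of indicators, one per
testable aspect of Findability, Accessibility, Interoperability and
Reusability. For computational biology the resource is not one thing but
four: the model file itself (its mathematical formulation in SBML or
CellML), the model's metadata, the COMBINE archive bundling model and
supporting files, and the archive's metadata. `faircombine` therefore
instantiates every RDA base indicator on both the model side and the
archive side: data-component indicators become *Model* and *Archive*
indicators, metadata-component indicators become *Model Metadata* (ID
suffix `MM`) and *Archive Metadata* (`MA`) indicators. With the 41 RDA
base indicators duplicated across sides and two additional
cross-community metadata indicators (`CA-RDA-R1.3-03MM`/`MA`), the
registry holds 84 indicators, 42 per side.

Scoring is binary at heart — 1 fulfilled, 0 not, NA when an indicator
does not apply to the context — with an intermediate 0.5 permitted only
in enumerated partial situations, to acknowledge information that exists
but does not fully satisfy the indicator (for example, standardized
provenance that lives on a repository record page rather than in a
separate metadata file). A manual 0.5 always requires a justification
note; the automatic checks produce 0.5 only in the partial situations
documented on each check.

The assessment is *semi-automatic*: checks propose scores for whatever
the archive's bytes and a declared repository context can prove, manual
scores override automatic proposals, and dependency rules then force
logically entailed scores. Indicators nothing covers remain `PENDING` in
a draft and must be resolved before finalization.

## The registry as data

The indicator set ships as an editable tab-separated file
(`inst/extdata/combine_fair_indicators.tsv`), one row per indicator with
its principle, ordinal, target, priority, description, default assessment
mode and origin. The loader enforces the structural invariants — 84
indicators, 42 per side, unique IDs, exactly two registry-new indicators,
exactly three priority levels, IDs consistent with the
`CA-RDA-<principle>-<ordinal><suffix>` grammar — and any violation is a
load error, so a seeding mistake cannot silently skew results. Priorities
follow the RDA source values. The two cross-community metadata indicators
are classed *Important* here: their closest sibling (the
machine-understandable community-standard indicator on the data side)
carries that priority in the RDA source, and no published COMBINE
re-prioritization of them is available. Both the registry file and the
dependency-rule table can be replaced at load time, so community
re-prioritizations are data edits, not code changes.

## What the checks can and cannot prove

Each automatic check is a pure, deterministic function of the parsed
archive, its metadata record, and the repository context:

- **Standard format**: the model entry's kind (SBML/CellML, detected from
  the OMEX format identifier, falling back to root-namespace sniffing)
  fulfils the community-standard indicator; the archive-side variant
  additionally requires a manifest-bearing OMEX container.
- **Separate metadata**: a parseable `metadata.rdf` (or any entry with
  the OMEX-metadata format identifier) scores 1; metadata existing only
  inline in the model, or only in the declared repository context, scores
  0.5.
- **Provenance**: creator plus a created/modified history in the separate
  metadata file scores 1; the same information available only through the
  repository scores 0.5.
- **Identifiers**: a DOI pattern or identifiers-registry URI scores 1, a
  local-only accession 0.5, none 0. Resolvability is judged offline by
  pattern — the package never touches the network. When the metadata
  carries no identifier but the declared repository mints persistent
  accessions, the proposal is left pending for a human rather than
  auto-scored, since the archive's bytes cannot prove it.
- **Access protocol and licence**: these are repository properties, so
  they come from the context declaration; a repository-wide licence
  yields a score with provenance `repository-default`. With no declared
  context the access indicators stay pending — absence of a declaration
  is not evidence of absence.
- **References**: a reference is *qualified* when it carries an explicit
  relation predicate (e.g. `dcterms:references`); a bare related-resource
  link (`dcterms:relation`, `rdfs:seeAlso`) is unqualified. This
  operationalization is a design choice: the distinction between the two
  indicators requires some notion of qualification, and the relation
  predicate is the machine-checkable one.
- **Cross-community metadata**: the RDF must use at least one recognized
  cross-community vocabulary (Dublin Core, PROV, FOAF, vCard, RDFS);
  RDF using only community-internal vocabularies scores 0.5.

All other indicators default to manual assessment. The checks never score
metadata *quality* — rich but uninformative metadata passes the existence
checks; judging informativeness has no mechanical procedure and is out of
scope.

## Dependency propagation

Rules are rows of a data table: antecedent, dependent, trigger (0) and
forced value (0). The shipped default contains only entailment-justified
pairs — references→qualified-references on the model and archive sides
and the analogous metadata-side pairs. Propagation iterates to a fixed
point; because rules only ever move a score to 0, the iteration is
monotone and terminates. Three deliberate policies:

- Not-applicable indicators are never forced: NA records a judgement that
  the indicator does not bear on this resource, which entailment between
  *scores* cannot override.
- A manual score may be overwritten only downward (non-zero to 0):
  propagation encodes logical impossibility, and a human cannot override
  an impossibility — so a propagated 0 is final.
- Cyclic rule tables are rejected up front (Kahn's algorithm) rather than
  risking order-dependent results.

## Aggregation

A slice percentage (per principle, per target) is
`100 × sum(scores) / n` over the non-NA indicators of the slice; NA is
excluded from every denominator, so adding a not-applicable indicator
never moves a percentage, and an all-NA slice reports NA rather than 0.
The overall percentage is the same statistic over all scored indicators,
equivalently the non-NA-count-weighted mean of the per-target
percentages. Priorities are reported (fraction fulfilled per level) but
do not weight the overall score: a weighted score would invite comparing
resources, and these scores are meaningful only for one resource over
time. Chart export emits one data row per indicator — target panel,
principle group, score, and the conventional colour key (F blue,
A orange, I green, R red) — leaving the plotting backend to the user.

Finalization is explicit. `PENDING` is allowed in drafts and forbidden in
finalized assessments; `finalize_assessment()` either errors on pending
indicators (the default, forcing complete manual coverage) or fills them
with 0 (conservative: unassessed treated as unfulfilled) or NA (excluded)
— the choice is recorded in each filled score's note.

## The synthetic fixtures

Five generator presets emulate the *metadata composition* of
repository-hosted models at different curation stages: three
BioModels-like stages (non-curated, curated, highly curated, all SBML
with a separate `metadata.rdf` and inline MIRIAM-style annotations,
progressively adding a modification history, qualified references,
SED-ML, a report, a DOI and an explicit licence) and two PMR-like stages
(CellML; the non-curated one with a session file and inline annotations
but no separate metadata; the curated one with SED-ML and a report but —
characteristically — no annotations inside the model files). The model
mathematics is a one-species placeholder; no check inspects model math.
Archives are written deterministically (fixed container timestamps,
seed-derived element IDs), so identical inputs give byte-identical
archives and reproducible failures.

What passing fixture tests shows — and what it does not: the fixtures
exercise the structural features the checks read (formats, manifest,
metadata vocabulary, references, identifiers), so they validate the
engine's logic end to end; they do not reproduce published assessments of
real repository-hosted models, whose scores also depend on repository
web pages, journal pages and human judgement that only the repository
context declaration can approximate here. Within each repository family
the presets are feature-monotone, and the test suite verifies that no
per-principle percentage decreases along the curation ladder (with
pending indicators filled as 0 so that only evidence-backed scores drive
the comparison).

## Numerical and degenerate-input choices

- Score values are carried as tokens (`"0"`, `"0.5"`, `"1"`, `"NA"`,
  `"PENDING"`), not floats, so NA-vs-pending is never ambiguous;
  aggregation maps them to numerics at the end.
- Reading never fails on content problems: a missing manifest falls back
  to the container listing, malformed RDF yields `parse_errors` on the
  metadata record (and therefore a 0 on checks that require parseable
  metadata), a bare model file becomes a single-entry pseudo-archive
  whose archive-side indicators score NA.
- Entry order follows the manifest, and report JSON is written with a
  fixed field order, so reruns on identical bytes are byte-identical.
- Problem sizes in the shipped tests: the full 84-indicator registry
  everywhere; propagation properties on 100 randomized acyclic rule
  tables over 84-node score maps; all five presets end to end. The whole
  suite runs in well under a minute.

## Known limitations

- Identifier resolvability is a pattern judgement; an indicator could be
  fulfilled by a resolvable URI the patterns miss (or vice versa). Online
  resolution is deliberately absent.
- The CellML annotation harvester reads MIRIAM-style qualifier blocks;
  other embedded metadata dialects count only toward
  `inline_metadata_present`.
- Only the enumerated checks are automated; a resource could merit better
  scores than a draft shows, which is exactly why finalization defaults
  to requiring manual input rather than guessing.
- Metadata informativeness is not scored, only presence and form.
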