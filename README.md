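# faircombine

Semi-automatic FAIR maturity assessment for systems-biology models and
COMBINE archives.

Computational models in biology are shared as SBML or CellML files,
typically bundled with simulation descriptions (SED-ML), diagrams
(SBGN-ML) and metadata into a COMBINE archive (OMEX: a ZIP container with
a `manifest.xml` and, conventionally, a `metadata.rdf`). How *FAIR* —
Findable, Accessible, Interoperable, Reusable — such a resource is can be
assessed against the RDA FAIR Data Maturity Model, but those indicators
speak about generic "data" and "metadata". `faircombine` implements the
COMBINE adaptation of that indicator set and a scoring engine around it,
for model curators, repository maintainers, and modellers who want to
find the weak points of their own archives before publishing.

## What it implements

- **An 84-indicator registry.** Each of the 41 RDA base indicators is
  instantiated on the model side and the archive side — the data-component
  indicators become *Model* / *Archive* indicators, the metadata-component
  ones become *Model Metadata* (`MM`) / *Archive Metadata* (`MA`)
  indicators — plus two COMBINE-specific Reusability indicators requiring
  metadata in a machine-understandable *cross-community* standard
  (`CA-RDA-R1.3-03MM`, `CA-RDA-R1.3-03MA`). Indicators carry a priority
  (Essential / Important / Useful) and an ID with the grammar
  `CA-RDA-<principle>-<ordinal><Model|MM|Archive|MA>`.
- **Scoring.** Each indicator is scored 1 (fulfilled), 0 (not fulfilled),
  NA (not applicable), or — in enumerated partial situations — 0.5, e.g.
  when provenance metadata exists but not in a separate file.
- **Automatic checks** over the parsed archive: standard model format,
  existence of separate metadata, standardized provenance, persistent
  identifiers (DOI / identifiers-registry URI patterns, offline),
  repository access protocol, licence (including repository-wide
  licences), references vs *qualified* references, and cross-community
  metadata vocabulary. Everything else stays `PENDING` for manual input.
- **Dependency propagation.** Logical entailments between indicators are
  data (a rule table): if an archive includes no references to other data
  (`CA-RDA-I3-01Archive` = 0), it cannot include qualified references
  either, so `CA-RDA-I3-02Archive` is forced to 0. Propagation runs to a
  fixed point, never raises a score, and skips not-applicable indicators.
- **Aggregation and export.** FAIRness percentages by principle, target
  and priority (NA excluded from every denominator), radial-column-chart
  rows (Findability blue, Accessibility orange, Interoperability green,
  Reusability red), and JSON/CSV/markdown reports that round-trip.
- **A fixture generator** for five synthetic archives emulating the
  metadata composition of repository-hosted models at different curation
  levels (three BioModels-like stages, two PMR-like stages), so the whole
  pipeline is testable offline.

## Worked example

```r
library(faircombine)

reg  <- load_registry()
path <- make_archive("highly_curated_biomodels_like",
                     tempfile(fileext = ".omex"))
arch <- read_archive(path)
arch
#> COMBINE archive: /tmp/.../file...omex
#>  entries: 5 | manifest: TRUE | bare model: FALSE
#>           location         kind is_master
#> 1     manifest.xml     MANIFEST     FALSE
#> 2        model.xml         SBML      TRUE
#> 3     metadata.rdf METADATA_RDF     FALSE
#> 4 simulation.sedml        SEDML     FALSE
#> 5       report.pdf        OTHER     FALSE

a <- run_assessment(arch, reg, repository_context("BioModels-like"))
fin <- finalize_assessment(a, pending = "zero", registry = reg)
aggregate_scores(fin, reg)
#> FAIRness summary
#>  overall: 20.2%
#>  by principle: F 42.9% | A 8.3% | I 8.3% | R 31.8%
#>  by target: Model 33.3% | ModelMetadata 14.8% | Archive 33.3% | ArchiveMetadata 11.1%
#>  scored: 84 | NA: 0 | partial (0.5): 0
```

The automatic checks fulfil what the archive's bytes and the declared
repository context can prove — the SBML model format (Reusability), the
DOI identifier (Findability), API access and free protocol
(Accessibility), the licence and provenance metadata — and the remaining
indicators were conservatively treated as non-fulfilled at finalization
(`pending = "zero"`), which is why the overall score is low: a realistic
baseline for a semi-automatic run without any curator input. Scores track
one resource over time; they are not comparable across resources.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/faircombine.R", package="faircombine"))')" \
    assess --input archive.omex --context BioModels-like --report report.json
```

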