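# Synthetic COMBINE archives emulating five curation-level categories.
#
# The five presets mirror the metadata composition of the assessed
# categories: three BioModels-like archives (non-curated, curated, highly
# curated) with a separate metadata.rdf and inline model annotations, and
# two PMR-like archives (non-curated with a session file and inline
# annotations; curated with SED-ML and a report but no inline
# annotations). Only the metadata structure is emulated — the model
# content is a minimal one-species placeholder, never inspected by any
# check.

.fc_presets <- list(
  noncurated_biomodels_like = list(
    name = "noncurated_biomodels_like", repository = "BioModels-like",
    model_format = "SBML", has_separate_metadata = TRUE,
    has_inline_annotations = TRUE, has_sedml = FALSE, has_report = FALSE,
    has_doi = FALSE, license_in_metadata = FALSE,
    has_qualified_reference = FALSE, has_modified_history = FALSE),
  curated_biomodels_like = list(
    name = "curated_biomodels_like", repository = "BioModels-like",
    model_format = "SBML", has_separate_metadata = TRUE,
    has_inline_annotations = TRUE, has_sedml = TRUE, has_report = FALSE,
    has_doi = FALSE, license_in_metadata = FALSE,
    has_qualified_reference = TRUE, has_modified_history = TRUE),
  highly_curated_biomodels_like = list(
    name = "highly_curated_biomodels_like", repository = "BioModels-like",
    model_format = "SBML", has_separate_metadata = TRUE,
    has_inline_annotations = TRUE, has_sedml = TRUE, has_report = TRUE,
    has_doi = TRUE, license_in_metadata = TRUE,
    has_qualified_reference = TRUE, has_modified_history = TRUE),
  noncurated_pmr_like = list(
    name = "noncurated_pmr_like", repository = "PMR-like",
    model_format = "CellML", has_separate_metadata = FALSE,
    has_inline_annotations = TRUE, has_sedml = FALSE, has_report = FALSE,
    has_doi = FALSE, license_in_metadata = FALSE,
    has_qualified_reference = FALSE, has_modified_history = FALSE),
  curated_pmr_like = list(
    name = "curated_pmr_like", repository = "PMR-like",
    model_format = "CellML", has_separate_metadata = FALSE,
    has_inline_annotations = FALSE, has_sedml = TRUE, has_report = TRUE,
    has_doi = TRUE, license_in_metadata = FALSE,
    has_qualified_reference = FALSE, has_modified_history = FALSE)
)

#' List the five fixture presets
#'
#' Returns the five synthetic archive presets emulating the assessed
#' curation-level categories (three BioModels-like stages and two PMR-like
#' stages). Each preset declares the model format and which metadata
#' components the generated archive carries.
#'
#' @return A named list of five preset definitions.
#' @examples
#' names(list_presets())
#' @export
list_presets <- function() {
  .fc_presets
}

.get_preset <- function(preset) {
  if (is.character(preset)) {
    if (!preset %in% names(.fc_presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(.fc_presets), collapse = ", "), call. = FALSE)
    }
    preset <- .fc_presets[[preset]]
  }
  preset
}

#' Generate a minimal model document
#'
#' Emits a well-formed single-species SBML or single-variable CellML
#' document. With annotations enabled, one MIRIAM-style annotation block
#' (a biology qualifier pointing at an identifiers-registry URI) is
#' embedded. Output is deterministic for fixed arguments.
#'
#' @param format `"SBML"` or `"CellML"`.
#' @param with_annotations Embed an annotation block?
#' @param seed Integer; varies element identifiers only.
#' @return A character scalar holding the document.
#' @export
make_model_file <- function(format = c("SBML", "CellML"),
                            with_annotations = TRUE, seed = 1L) {
  format <- match.arg(format)
  seed <- as.integer(seed)
  mid <- sprintf("synthetic_model_%04d", seed %% 10000L)
  if (format == "SBML") {
    ann <- if (with_annotations) paste0(
      '      <annotation>\n',
      '        <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
      '                 xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">\n',
      '          <rdf:Description rdf:about="#', mid, '_s1">\n',
      '            <bqbiol:is>\n',
      '              <rdf:Bag>\n',
      '                <rdf:li rdf:resource="https://identifiers.org/CHEBI:17234"/>\n',
      '              </rdf:Bag>\n',
      '            </bqbiol:is>\n',
      '          </rdf:Description>\n',
      '        </rdf:RDF>\n',
      '      </annotation>\n') else ""
    return(paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
      'level="3" version="2">\n',
      '  <model id="', mid, '" name="Synthetic placeholder model">\n',
      '    <listOfCompartments>\n',
      '      <compartment id="cell" constant="true"/>\n',
      '    </listOfCompartments>\n',
      '    <listOfSpecies>\n',
      '      <species id="', mid, '_s1" compartment="cell" ',
      'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false">\n',
      ann,
      '      </species>\n',
      '    </listOfSpecies>\n',
      '  </model>\n',
      '</sbml>\n'))
  }
  ann <- if (with_annotations) paste0(
    '  <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '           xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">\n',
    '    <rdf:Description rdf:about="#', mid, '">\n',
    '      <bqbiol:isVersionOf rdf:resource="https://identifiers.org/GO:0006412"/>\n',
    '    </rdf:Description>\n',
    '  </rdf:RDF>\n') else ""
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<model xmlns="http://www.cellml.org/cellml/1.1#" ',
    'xmlns:cmeta="http://www.cellml.org/metadata/1.0#" ',
    'name="', mid, '" cmeta:id="', mid, '">\n',
    ann,
    '  <component name="main">\n',
    '    <variable name="x" units="dimensionless" initial_value="1"/>\n',
    '  </component>\n',
    '</model>\n')
}

.make_sedml <- function(model_location) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sedML xmlns="http://sed-ml.org/sed-ml/level1/version3" ',
    'level="1" version="3">\n',
    '  <listOfModels>\n',
    '    <model id="m1" language="urn:sedml:language:sbml" source="',
    model_location, '"/>\n',
    '  </listOfModels>\n',
    '</sedML>\n')
}

.make_metadata_rdf <- function(preset, seed, corrupt = FALSE) {
  doi <- "https://doi.org/10.36903/synthetic.00001"
  local_id <- sprintf("ARCHIVE-LOCAL-%04d", as.integer(seed) %% 10000L)
  refs <- c(
    '    <rdfs:seeAlso rdf:resource="https://example.org/related-dataset"/>')
  if (isTRUE(preset$has_qualified_reference)) {
    refs <- c(refs, paste0(
      '    <dcterms:references ',
      'rdf:resource="https://identifiers.org/pubmed/10659856"/>'))
  }
  body <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
    '         xmlns:dcterms="http://purl.org/dc/terms/">\n',
    '  <rdf:Description rdf:about=".">\n',
    '    <dcterms:description>Synthetic archive emulating a curation ',
    'category</dcterms:description>\n',
    '    <dcterms:creator>Synthetic Curator</dcterms:creator>\n',
    '    <dcterms:created>\n',
    '      <rdf:Description>\n',
    '        <dcterms:W3CDTF>2022-10-01T00:00:00Z</dcterms:W3CDTF>\n',
    '      </rdf:Description>\n',
    '    </dcterms:created>\n',
    if (isTRUE(preset$has_modified_history)) paste0(
      '    <dcterms:modified>\n',
      '      <rdf:Description>\n',
      '        <dcterms:W3CDTF>2023-02-15T00:00:00Z</dcterms:W3CDTF>\n',
      '      </rdf:Description>\n',
      '    </dcterms:modified>\n') else "",
    '    <dcterms:identifier>',
    if (isTRUE(preset$has_doi)) doi else local_id,
    '</dcterms:identifier>\n',
    paste0(refs, collapse = "\n"), "\n",
    if (isTRUE(preset$license_in_metadata)) paste0(
      '    <dcterms:license rdf:resource=',
      '"https://creativecommons.org/licenses/by/4.0/"/>\n') else "",
    '  </rdf:Description>\n',
    '</rdf:RDF>\n')
  if (corrupt) body <- substr(body, 1, nchar(body) %/% 2L)
  body
}

.format_uri <- c(
  SBML = "http://identifiers.org/combine.specifications/sbml",
  CellML = "http://identifiers.org/combine.specifications/cellml",
  SEDML = "http://identifiers.org/combine.specifications/sed-ml",
  METADATA = "http://identifiers.org/combine.specifications/omex-metadata",
  MANIFEST = "http://identifiers.org/combine.specifications/omex-manifest",
  OMEX = "http://identifiers.org/combine.specifications/omex",
  PDF = "http://purl.org/NET/mediatypes/application/pdf",
  XML = "http://purl.org/NET/mediatypes/application/xml")

.make_manifest <- function(locations, formats, master) {
  rows <- sprintf(
    '  <content location="./%s" format="%s"%s/>', locations, formats,
    ifelse(master, ' master="true"', ''))
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<omexManifest xmlns=',
    '"http://identifiers.org/combine.specifications/omex-manifest">\n',
    '  <content location="." format="', .format_uri[["OMEX"]], '"/>\n',
    '  <content location="./manifest.xml" format="',
    .format_uri[["MANIFEST"]], '"/>\n',
    paste0(rows, collapse = "\n"), "\n",
    '</omexManifest>\n')
}

#' Materialize a fixture preset as an OMEX archive
#'
#' Writes a valid OMEX archive (ZIP container with `manifest.xml`) whose
#' entries follow the preset's declared metadata composition. Reading the
#' result with [read_archive()] recovers exactly the declared structure.
#' Generation is deterministic for fixed `(preset, seed)`.
#'
#' @param preset Preset name or definition from [list_presets()].
#' @param destination Output file path (defaults to a file named after the
#'   preset in `tempdir()`).
#' @param seed Integer seed varying only internal identifiers.
#' @param corrupt_metadata Internal testing hook: write a truncated,
#'   unparseable metadata entry for robustness tests.
#' @return The path to the written archive.
#' @examples
#' path <- make_archive("curated_pmr_like", tempfile(fileext = ".omex"))
#' read_archive(path)
#' @export
make_archive <- function(preset, destination = NULL, seed = 1L,
                         corrupt_metadata = FALSE) {
  preset <- .get_preset(preset)
  if (is.null(destination)) {
    destination <- file.path(tempdir(), paste0(preset$name, ".omex"))
  }
  dir <- dirname(destination)
  if (!dir.exists(dir)) {
    stop("destination directory does not exist: ", dir, call. = FALSE)
  }
  model_loc <- if (preset$model_format == "SBML") "model.xml"
               else "model.cellml"
  entries <- list()
  locations <- character(); formats <- character(); master <- logical()
  add <- function(loc, fmt, is_master = FALSE, content) {
    entries[[loc]] <<- content
    locations <<- c(locations, loc)
    formats <<- c(formats, fmt)
    master <<- c(master, is_master)
  }
  add(model_loc, .format_uri[[preset$model_format]], TRUE,
      make_model_file(preset$model_format, preset$has_inline_annotations,
                      seed))
  if (isTRUE(preset$has_separate_metadata)) {
    add("metadata.rdf", .format_uri[["METADATA"]], FALSE,
        .make_metadata_rdf(preset, seed, corrupt = corrupt_metadata))
  }
  if (isTRUE(preset$has_sedml)) {
    add("simulation.sedml", .format_uri[["SEDML"]], FALSE,
        .make_sedml(model_loc))
  }
  if (isTRUE(preset$has_report)) {
    add("report.pdf", .format_uri[["PDF"]], FALSE,
        "Synthetic curation report placeholder (plain text standing in for a PDF).")
  }
  if (identical(preset$repository, "PMR-like") &&
      !isTRUE(preset$has_separate_metadata)) {
    add("session.xml", .format_uri[["XML"]], FALSE,
        paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
               '<session><view model="', model_loc, '"/></session>\n'))
  }
  manifest <- .make_manifest(locations, formats, master)
  zip_entries <- c(list(manifest.xml = manifest), entries)
  .write_zip(destination, zip_entries)
  destination
}
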