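# Reading COMBINE archives (OMEX) and bare model files.
#
# An OMEX archive is a ZIP container with a manifest.xml whose <content>
# elements carry location / format / master attributes, optionally plus an
# RDF/XML metadata entry (conventionally "metadata.rdf"). A bare SBML or
# CellML file is wrapped as a single-entry pseudo-archive so model-target
# indicators can be assessed without an archive.

.fc_kinds <- c("SBML", "CellML", "SEDML", "SBGNML", "METADATA_RDF",
               "MANIFEST", "OTHER")

.ns_rdf <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
# cross-community description vocabularies recognized for the R1.3-03
# indicators (machine-understandable cross-community standard)
.cross_community_ns <- c(
  "http://purl.org/dc/terms/",
  "http://purl.org/dc/elements/1.1/",
  "http://www.w3.org/ns/prov#",
  "http://xmlns.com/foaf/0.1/",
  "http://www.w3.org/2006/vcard/ns#",
  "http://www.w3.org/2001/vcard-rdf/3.0#",
  "http://www.w3.org/2000/01/rdf-schema#"
)

#' Detect the kind of an archive entry
#'
#' Classifies an entry by its OMEX format identifier first; if that is
#' absent or unrecognized, falls back to sniffing the root-element XML
#' namespace of the content. Unknown content maps to `"OTHER"` — detection
#' never fails.
#'
#' @param format_id Format identifier URI from the manifest, or `NA`.
#' @param content Entry content as a raw vector or character string, or
#'   `NULL` if unavailable.
#' @return One of `"SBML"`, `"CellML"`, `"SEDML"`, `"SBGNML"`,
#'   `"METADATA_RDF"`, `"MANIFEST"`, `"OTHER"`.
#' @examples
#' detect_entry_format("http://identifiers.org/combine.specifications/sbml",
#'                     NULL)
#' @export
detect_entry_format <- function(format_id, content = NULL) {
  if (!is.null(format_id) && length(format_id) == 1L && !is.na(format_id) &&
      nzchar(format_id)) {
    f <- tolower(format_id)
    if (grepl("combine\\.specifications/sbml", f)) return("SBML")
    if (grepl("combine\\.specifications/cellml", f)) return("CellML")
    if (grepl("combine\\.specifications/sed-?ml", f)) return("SEDML")
    if (grepl("combine\\.specifications/sbgn", f)) return("SBGNML")
    if (grepl("combine\\.specifications/omex-metadata", f)) {
      return("METADATA_RDF")
    }
    if (grepl("combine\\.specifications/omex-manifest", f)) return("MANIFEST")
    if (grepl("mediatypes?/application/rdf\\+xml", f)) return("METADATA_RDF")
  }
  .sniff_kind(content)
}

.sniff_kind <- function(content) {
  if (is.null(content) || (is.logical(content) && all(is.na(content)))) {
    return("OTHER")
  }
  doc <- tryCatch(xml2::read_xml(content), error = function(e) NULL)
  if (is.null(doc)) return("OTHER")
  root <- xml2::xml_root(doc)
  nss <- tryCatch(unlist(xml2::xml_ns(doc)), error = function(e) character())
  name <- xml2::xml_name(root)
  has_ns <- function(pat) any(grepl(pat, nss, fixed = TRUE))
  if (name == "sbml" && has_ns("sbml.org")) return("SBML")
  if (name == "model" && has_ns("cellml.org")) return("CellML")
  if (name == "sedML" || has_ns("sed-ml.org")) return("SEDML")
  if (name == "sbgn" || has_ns("sbgn.org")) return("SBGNML")
  if (name == "omexManifest") return("MANIFEST")
  if (name == "RDF" && has_ns(.ns_rdf)) return("METADATA_RDF")
  "OTHER"
}

#' Read a COMBINE archive or a bare model file
#'
#' Reads an OMEX archive (ZIP container): entries are enumerated from
#' `manifest.xml` in manifest order when present, otherwise from the
#' container listing; any OMEX-metadata entry is parsed into a metadata
#' record. A bare SBML or CellML file is wrapped as a single-entry
#' pseudo-archive. Content problems (missing manifest, malformed RDF) never
#' abort reading — they surface as features the indicator checks score.
#'
#' @param path Path to an OMEX archive (ZIP) or a model file.
#' @return A `combine_archive` object with elements `entries` (data frame:
#'   `location`, `format_id`, `is_master`, `kind`), `has_manifest`,
#'   `metadata` (a `metadata_record`), `source_path`, `bare`, and
#'   `contents` (named list of raw vectors).
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (.is_zip(path)) {
    arch <- .read_omex(path)
  } else {
    arch <- .read_bare_model(path)
  }
  arch$metadata <- extract_metadata(arch)
  arch
}

.read_omex <- function(path) {
  exdir <- tempfile("omex_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir, unzip = "internal")
  listing <- utils::unzip(path, list = TRUE, unzip = "internal")$Name
  listing <- listing[!endsWith(listing, "/")]
  read_entry <- function(loc) {
    f <- file.path(exdir, loc)
    if (!file.exists(f)) return(NULL)
    readBin(f, "raw", n = file.info(f)$size)
  }
  manifest_loc <- listing[basename(listing) == "manifest.xml"]
  entries <- NULL
  has_manifest <- FALSE
  if (length(manifest_loc)) {
    man <- tryCatch(xml2::read_xml(read_entry(manifest_loc[1])),
                    error = function(e) NULL)
    if (!is.null(man)) {
      contents <- xml2::xml_find_all(man, ".//*[local-name() = 'content']")
      if (length(contents)) {
        has_manifest <- TRUE
        entries <- data.frame(
          location = xml2::xml_attr(contents, "location"),
          format_id = xml2::xml_attr(contents, "format"),
          is_master = tolower(xml2::xml_attr(contents, "master")) %in% "true",
          stringsAsFactors = FALSE)
        entries$location <- sub("^\\./", "", entries$location)
        # the archive's own self-entry is the container, not content
        entries <- entries[!entries$location %in% c(".", ""), , drop = FALSE]
      }
    }
  }
  if (!has_manifest) {
    entries <- data.frame(location = listing, format_id = NA_character_,
                          is_master = FALSE, stringsAsFactors = FALSE)
  }
  entries <- entries[!duplicated(entries$location), , drop = FALSE]
  contents <- lapply(entries$location, read_entry)
  names(contents) <- entries$location
  entries$kind <- vapply(seq_len(nrow(entries)), function(i) {
    detect_entry_format(entries$format_id[i], contents[[i]])
  }, character(1))
  rownames(entries) <- NULL
  structure(list(entries = entries, has_manifest = has_manifest,
                 metadata = NULL, source_path = path, bare = FALSE,
                 contents = contents),
            class = "combine_archive")
}

.read_bare_model <- function(path) {
  content <- readBin(path, "raw", n = file.info(path)$size)
  kind <- .sniff_kind(content)
  if (!kind %in% c("SBML", "CellML", "SEDML", "SBGNML")) {
    stop("not a ZIP container and not a recognizable model file: ", path,
         call. = FALSE)
  }
  entries <- data.frame(location = basename(path), format_id = NA_character_,
                        is_master = TRUE, kind = kind,
                        stringsAsFactors = FALSE)
  contents <- list(content)
  names(contents) <- entries$location
  structure(list(entries = entries, has_manifest = FALSE, metadata = NULL,
                 source_path = path, bare = TRUE, contents = contents),
            class = "combine_archive")
}

#' @export
print.combine_archive <- function(x, ...) {
  cat("COMBINE archive:", x$source_path, "\n")
  cat(" entries:", nrow(x$entries),
      "| manifest:", x$has_manifest,
      "| bare model:", x$bare, "\n")
  print(x$entries[, c("location", "kind", "is_master")])
  invisible(x)
}

.empty_metadata_record <- function(has_file = FALSE) {
  structure(list(
    has_separate_metadata_file = has_file,
    creators = character(),
    created = NA_character_,
    modified = character(),
    description = NA_character_,
    identifiers = character(),
    references = data.frame(target = character(), predicate = character(),
                            stringsAsFactors = FALSE),
    license = NA_character_,
    provenance_statements = data.frame(subject = character(),
                                       predicate = character(),
                                       object = character(),
                                       stringsAsFactors = FALSE),
    vocab_namespaces = character(),
    parse_errors = character()
  ), class = "metadata_record")
}

# reference predicates: those carrying an explicit relation semantics count
# as qualified; bare "related/see-also" links do not
.qualified_ref_terms <- c("references", "isVersionOf", "isPartOf", "hasPart",
                          "source", "isReferencedBy", "isDescribedBy")
.unqualified_ref_terms <- c("relation", "seeAlso")

#' Extract the separate metadata record of an archive
#'
#' Parses any OMEX-metadata entry (RDF/XML) into a structured record:
#' creators, creation/modification timestamps, description, identifiers,
#' references (with their relation predicate when one is given), license,
#' and a flat list of all statements. Malformed RDF populates
#' `parse_errors` and returns a partial record; nothing raises.
#'
#' @param archive A `combine_archive` from [read_archive()].
#' @return A `metadata_record`.
#' @export
extract_metadata <- function(archive) {
  stopifnot(inherits(archive, "combine_archive"))
  idx <- which(archive$entries$kind == "METADATA_RDF" |
                 basename(archive$entries$location) == "metadata.rdf")
  if (length(idx) == 0L) return(.empty_metadata_record(FALSE))
  rec <- .empty_metadata_record(TRUE)
  for (i in idx) {
    content <- archive$contents[[archive$entries$location[i]]]
    if (is.null(content)) {
      rec$parse_errors <- c(rec$parse_errors, paste0(
        "metadata entry '", archive$entries$location[i],
        "' declared in manifest but missing from container"))
      next
    }
    doc <- tryCatch(xml2::read_xml(content), error = function(e) e)
    if (inherits(doc, "error")) {
      rec$parse_errors <- c(rec$parse_errors, paste0(
        "metadata entry '", archive$entries$location[i],
        "' failed to parse as RDF/XML: ", conditionMessage(doc)))
      next
    }
    rec <- .harvest_rdf(doc, rec)
  }
  rec
}

.harvest_rdf <- function(doc, rec) {
  descs <- xml2::xml_find_all(doc, ".//*[local-name() = 'Description']")
  for (d in descs) {
    subject <- xml2::xml_attr(d, "about")
    if (is.na(subject)) subject <- ""
    for (child in xml2::xml_children(d)) {
      ns <- .node_ns_url(child)
      local <- xml2::xml_name(child)
      obj <- xml2::xml_attr(child, "resource")
      if (is.na(obj)) {
        obj <- trimws(xml2::xml_text(child))
      }
      rec$provenance_statements <- rbind(
        rec$provenance_statements,
        data.frame(subject = subject, predicate = paste0(ns, local),
                   object = obj, stringsAsFactors = FALSE))
      if (nzchar(ns)) {
        rec$vocab_namespaces <- unique(c(rec$vocab_namespaces, ns))
      }
      dc <- ns %in% c("http://purl.org/dc/terms/",
                      "http://purl.org/dc/elements/1.1/")
      if (dc && local == "creator") {
        rec$creators <- c(rec$creators, .creator_label(child))
      } else if (dc && local == "created") {
        rec$created <- .date_text(child)
      } else if (dc && local == "modified") {
        rec$modified <- c(rec$modified, .date_text(child))
      } else if (dc && local == "description") {
        rec$description <- obj
      } else if (dc && local == "identifier") {
        rec$identifiers <- c(rec$identifiers, obj)
      } else if (dc && local %in% c("license", "rights")) {
        rec$license <- obj
      } else if (dc && local %in% .qualified_ref_terms) {
        rec$references <- rbind(rec$references, data.frame(
          target = obj, predicate = paste0("dcterms:", local),
          stringsAsFactors = FALSE))
      } else if ((dc && local %in% .unqualified_ref_terms) ||
                 (ns == "http://www.w3.org/2000/01/rdf-schema#" &&
                    local == "seeAlso")) {
        rec$references <- rbind(rec$references, data.frame(
          target = obj, predicate = NA_character_, stringsAsFactors = FALSE))
      }
    }
  }
  rec
}

.node_ns_url <- function(node) {
  nsmap <- tryCatch(xml2::xml_ns(node), error = function(e) NULL)
  if (is.null(nsmap)) return("")
  qn <- tryCatch(xml2::xml_name(node, ns = nsmap),
                 error = function(e) xml2::xml_name(node))
  if (grepl(":", qn)) {
    prefix <- sub(":.*$", "", qn)
    url <- unclass(nsmap)[prefix]
    if (!is.na(url)) return(unname(url))
  }
  ""
}

.creator_label <- function(node) {
  txt <- trimws(xml2::xml_text(node))
  if (nzchar(txt)) return(gsub("\\s+", " ", txt))
  res <- xml2::xml_attr(node, "resource")
  if (!is.na(res)) return(res)
  "unnamed creator"
}

.date_text <- function(node) {
  # dcterms dates are either literal text or a nested W3CDTF element
  w3c <- xml2::xml_find_first(node, ".//*[local-name() = 'W3CDTF']")
  if (!inherits(w3c, "xml_missing")) return(trimws(xml2::xml_text(w3c)))
  trimws(xml2::xml_text(node))
}

.ns_bqbiol <- "http://biomodels.net/biology-qualifiers/"
.ns_bqmodel <- "http://biomodels.net/model-qualifiers/"

#' Extract embedded annotations from a model entry
#'
#' Collects MIRIAM-style annotations (controlled-registry URIs with their
#' biology/model qualifiers) from the RDF blocks embedded in an SBML or
#' CellML document.
#'
#' @param entry A one-row entry data frame (or list) with at least a `kind`
#'   field; must be an SBML or CellML entry.
#' @param content The entry content (raw vector or character).
#' @return An `annotation_set`: list with `uris`, `qualifiers` (parallel
#'   character vectors) and `inline_metadata_present`.
#' @export
extract_model_annotations <- function(entry, content) {
  kind <- if (is.data.frame(entry)) entry$kind[1] else entry$kind
  if (!kind %in% c("SBML", "CellML")) {
    stop("annotations can only be extracted from SBML or CellML entries, ",
         "got kind '", kind, "'", call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(content), error = function(e) NULL)
  empty <- structure(list(uris = character(), qualifiers = character(),
                          inline_metadata_present = FALSE),
                     class = "annotation_set")
  if (is.null(doc)) return(empty)
  rdf_blocks <- xml2::xml_find_all(
    doc, sprintf(".//*[local-name() = 'RDF' and namespace-uri() = '%s']",
                 .ns_rdf))
  ann_blocks <- xml2::xml_find_all(doc, ".//*[local-name() = 'annotation']")
  inline <- length(rdf_blocks) > 0L || length(ann_blocks) > 0L
  uris <- character()
  quals <- character()
  for (block in rdf_blocks) {
    preds <- xml2::xml_find_all(
      block, sprintf(
        ".//*[namespace-uri() = '%s' or namespace-uri() = '%s']",
        .ns_bqbiol, .ns_bqmodel))
    for (p in preds) {
      prefix <- if (identical(.node_ns_url(p), .ns_bqmodel)) {
        "bqmodel"
      } else {
        "bqbiol"
      }
      label <- paste0(prefix, ":", xml2::xml_name(p))
      res <- xml2::xml_attr(p, "resource")
      lis <- xml2::xml_find_all(p, ".//*[local-name() = 'li']")
      li_uris <- xml2::xml_attr(lis, "resource")
      found <- c(if (!is.na(res)) res, li_uris[!is.na(li_uris)])
      uris <- c(uris, found)
      quals <- c(quals, rep(label, length(found)))
    }
  }
  structure(list(uris = uris, qualifiers = quals,
                 inline_metadata_present = inline),
            class = "annotation_set")
}

# master model entry of an archive (first master SBML/CellML entry, else
# first model entry)
.model_entry <- function(archive) {
  e <- archive$entries
  models <- e[e$kind %in% c("SBML", "CellML"), , drop = FALSE]
  if (nrow(models) == 0L) return(NULL)
  masters <- models[models$is_master, , drop = FALSE]
  if (nrow(masters)) masters[1, , drop = FALSE] else models[1, , drop = FALSE]
}

.archive_annotations <- function(archive) {
  me <- .model_entry(archive)
  if (is.null(me)) {
    return(structure(list(uris = character(), qualifiers = character(),
                          inline_metadata_present = FALSE),
                     class = "annotation_set"))
  }
  extract_model_annotations(me, archive$contents[[me$location]])
}
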