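# Automatic indicator checks.
#
# Each check is a pure function of the parsed archive, its metadata record
# and the declared repository context, and proposes a score for one or more
# indicators with evidence and a rationale. Scores use the assessment
# scale: "1" fulfilled, "0" not fulfilled, "0.5" partial (only for the
# enumerated partial situations), "NA" not applicable, "PENDING" not
# automatically assessable (manual input required).

.score_tokens <- c("0", "0.5", "1", "NA", "PENDING")

.check_result <- function(indicator_id, proposed_score, rationale,
                          evidence = character(),
                          provenance = "automatic") {
  stopifnot(proposed_score %in% .score_tokens, nzchar(rationale))
  data.frame(indicator_id = indicator_id, proposed_score = proposed_score,
             rationale = rationale,
             evidence = paste(evidence, collapse = "; "),
             provenance = provenance, stringsAsFactors = FALSE)
}

.as_archive_entries <- function(x) {
  if (inherits(x, "combine_archive")) x$entries else x
}

#' Check use of COMBINE standard formats
#'
#' Model target: fulfilled when the (master) model entry is encoded in a
#' COMBINE community standard (SBML or CellML). Archive target: fulfilled
#' when the container is an OMEX archive (manifest present) whose model
#' entry is in a standard format.
#'
#' @param archive A `combine_archive` (or its `entries` data frame; then
#'   `has_manifest` must be supplied for the archive target).
#' @param target `"Model"` or `"Archive"`.
#' @param has_manifest Manifest presence, only needed when `archive` is a
#'   bare entries data frame.
#' @return A one-row check-result data frame.
#' @export
check_standard_format <- function(archive, target = c("Model", "Archive"),
                                  has_manifest = NA) {
  target <- match.arg(target)
  entries <- .as_archive_entries(archive)
  if (inherits(archive, "combine_archive")) has_manifest <- archive$has_manifest
  models <- entries[entries$kind %in% c("SBML", "CellML"), , drop = FALSE]
  master <- models[models$is_master, , drop = FALSE]
  model <- if (nrow(master)) master[1, ] else if (nrow(models)) models[1, ]
           else NULL
  id <- derive_target_id("R1.3-01", target)
  if (target == "Model") {
    if (!is.null(model)) {
      return(.check_result(id, "1",
        paste0("model entry is encoded in the ", model$kind,
               " community standard"),
        evidence = model$location))
    }
    return(.check_result(id, "0",
      "no model entry in a COMBINE standard format (SBML/CellML) found",
      evidence = entries$location))
  }
  if (isTRUE(has_manifest) && !is.null(model)) {
    return(.check_result(id, "1",
      paste0("OMEX container with manifest; model entry in ", model$kind),
      evidence = c("manifest.xml", model$location)))
  }
  .check_result(id, "0",
    if (!isTRUE(has_manifest)) {
      "container is not a manifest-bearing OMEX archive"
    } else {
      "no model entry in a COMBINE standard format inside the archive"
    },
    evidence = entries$location)
}

#' Check existence of a separate metadata file
#'
#' Fulfilled when a separate, parseable metadata file exists for the
#' target; partial (0.5) when metadata exists only inline in the model
#' file, or only through a declared repository context; 0 otherwise.
#'
#' @param archive A `combine_archive`.
#' @param target `"ModelMetadata"` or `"ArchiveMetadata"`.
#' @param context A [repository_context()].
#' @return A one-row check-result data frame.
#' @export
check_separate_metadata <- function(archive,
                                    target = c("ModelMetadata",
                                               "ArchiveMetadata"),
                                    context = repository_context("none")) {
  target <- match.arg(target)
  id <- derive_target_id("F2-01", target)
  md <- archive$metadata
  if (md$has_separate_metadata_file && length(md$parse_errors) == 0L) {
    loc <- archive$entries$location[
      archive$entries$kind == "METADATA_RDF" |
        basename(archive$entries$location) == "metadata.rdf"]
    return(.check_result(id, "1",
      "separate, parseable metadata file present in the archive",
      evidence = loc))
  }
  inline <- target == "ModelMetadata" &&
    .archive_annotations(archive)$inline_metadata_present
  if (inline) {
    return(.check_result(id, "0.5",
      paste0("metadata exists only inline in the model file, not as a ",
             "separate metadata file"),
      evidence = .model_entry(archive)$location))
  }
  if (context$name != "none") {
    return(.check_result(id, "0.5",
      paste0("metadata available only through the declared repository ",
             "context (", context$name, "), not as a separate file"),
      evidence = paste0("context:", context$name)))
  }
  .check_result(id, "0", "no metadata found for this target")
}

#' Check standardized provenance information
#'
#' Fulfilled when standardized provenance statements (creator plus a
#' creation/modification history) are present in a separate metadata file;
#' partial (0.5) when standardized provenance exists but not in a separate
#' file (e.g. only on the repository's record pages); 0 otherwise.
#'
#' @param metadata A `metadata_record`.
#' @param context A [repository_context()].
#' @param target `"ModelMetadata"` or `"ArchiveMetadata"`.
#' @return A one-row check-result data frame.
#' @export
check_provenance <- function(metadata, context = repository_context("none"),
                             target = c("ModelMetadata",
                                        "ArchiveMetadata")) {
  target <- match.arg(target)
  id <- derive_target_id("R1.2-01", target)
  in_file <- metadata$has_separate_metadata_file &&
    length(metadata$parse_errors) == 0L &&
    length(metadata$creators) > 0L &&
    (!is.na(metadata$created) || length(metadata$modified) > 0L)
  if (in_file) {
    ev <- c(paste0("creators: ", paste(metadata$creators, collapse = ", ")),
            if (!is.na(metadata$created)) paste0("created: ", metadata$created),
            if (length(metadata$modified)) {
              paste0("modified: ", paste(metadata$modified, collapse = ", "))
            })
    return(.check_result(id, "1",
      "standardized provenance (creator and date history) in a separate metadata file",
      evidence = ev))
  }
  if (context$name != "none" && isTRUE(context$provides_provenance)) {
    return(.check_result(id, "0.5",
      paste0("standardized provenance is available via the repository (",
             context$name, ") but the metadata is not available in ",
             "separate files"),
      evidence = paste0("context:", context$name)))
  }
  .check_result(id, "0", "no standardized provenance information found")
}

.doi_pattern <- "(^|/|:)10\\.[0-9]{4,9}/"
.is_global_id <- function(x) {
  grepl(.doi_pattern, x) | grepl("^https?://(dx\\.)?doi\\.org/", x) |
    grepl("identifiers\\.org/", x)
}

#' Check persistent / globally unique identifiers
#'
#' For the identifier-family indicators on the model and archive targets:
#' fulfilled when a globally resolvable identifier (DOI pattern or an
#' identifiers-registry URI) is attached to the resource; partial (0.5)
#' when only a local/internal identifier exists; 0 when none. When no
#' identifier is found but the declared repository mints persistent
#' accessions, the proposal is left pending for manual confirmation.
#'
#' @param archive A `combine_archive`.
#' @param metadata A `metadata_record`.
#' @param context A [repository_context()].
#' @return A check-result data frame (four rows: F1-01 and F1-02 on the
#'   Model and Archive targets).
#' @export
check_identifiers <- function(archive, metadata,
                              context = repository_context("none")) {
  ids <- metadata$identifiers
  ids <- ids[nzchar(ids)]
  global <- ids[.is_global_id(ids)]
  local <- setdiff(ids, global)
  one <- function(indicator_id) {
    if (length(global)) {
      .check_result(indicator_id, "1",
        "globally resolvable identifier attached (DOI / identifiers-registry URI)",
        evidence = global)
    } else if (length(local)) {
      .check_result(indicator_id, "0.5",
        "only a local/internal identifier is attached; it is not globally resolvable",
        evidence = local)
    } else if (isTRUE(context$assigns_persistent_ids) &&
               context$name != "none") {
      .check_result(indicator_id, "PENDING",
        paste0("no identifier in the archive metadata; the repository (",
               context$name, ") mints accessions - confirm manually"),
        evidence = paste0("context:", context$name))
    } else {
      .check_result(indicator_id, "0", "no identifier of any kind attached")
    }
  }
  do.call(rbind, lapply(c("CA-RDA-F1-01Model", "CA-RDA-F1-01Archive",
                          "CA-RDA-F1-02Model", "CA-RDA-F1-02Archive"), one))
}

#' Check repository access protocol indicators
#'
#' Fulfilled from the repository context: automatic (API) access fulfils
#' the automatic-access indicator, a free access protocol fulfils the
#' free-protocol indicator. Without a declared context both proposals are
#' left pending for manual assessment.
#'
#' @param context A [repository_context()].
#' @return A check-result data frame (two rows: `CA-RDA-A1-05Model`,
#'   `CA-RDA-A1.1-01Model`).
#' @export
check_access_protocol <- function(context = repository_context("none")) {
  if (context$name == "none") {
    return(rbind(
      .check_result("CA-RDA-A1-05Model", "PENDING",
        "no repository context declared; access route unknown"),
      .check_result("CA-RDA-A1.1-01Model", "PENDING",
        "no repository context declared; access protocol unknown")))
  }
  rbind(
    .check_result("CA-RDA-A1-05Model",
      if (isTRUE(context$has_api_access)) "1" else "0",
      if (isTRUE(context$has_api_access)) {
        paste0("repository (", context$name,
               ") provides API access to the model")
      } else {
        paste0("repository (", context$name, ") declares no API access")
      },
      evidence = paste0("context:", context$name)),
    .check_result("CA-RDA-A1.1-01Model",
      if (isTRUE(context$has_free_protocol)) "1" else "0",
      if (isTRUE(context$has_free_protocol)) {
        paste0("repository (", context$name,
               ") serves the model over a free access protocol")
      } else {
        paste0("repository (", context$name,
               ") declares no free access protocol")
      },
      evidence = paste0("context:", context$name)))
}

#' Check licence information
#'
#' Fulfilled when the metadata carries an explicit licence, or when the
#' declared repository applies an overall licence to all hosted resources
#' (then the score provenance is `repository-default`).
#'
#' @param metadata A `metadata_record`.
#' @param context A [repository_context()].
#' @return A one-row check-result data frame for `CA-RDA-R1.1-01MM`.
#' @export
check_license <- function(metadata, context = repository_context("none")) {
  id <- "CA-RDA-R1.1-01MM"
  if (!is.na(metadata$license)) {
    return(.check_result(id, "1",
      "explicit licence statement in the metadata file",
      evidence = metadata$license))
  }
  if (!is.na(context$repository_license) && context$name != "none") {
    return(.check_result(id, "1",
      paste0("repository-wide licence (", context$repository_license,
             ") applies to all hosted resources"),
      evidence = paste0("context:", context$name),
      provenance = "repository-default"))
  }
  .check_result(id, "0", "no licence information found")
}

#' Check references and qualified references
#'
#' The references indicator is fulfilled when the metadata lists at least
#' one reference to other data; the qualified-references indicator
#' additionally requires at least one reference carrying an explicit
#' relation predicate. When no references exist at all, the qualified
#' indicator is logically entailed to be non-fulfilled as well (this pair
#' is also in the default dependency table).
#'
#' @param metadata A `metadata_record`.
#' @param target `"Archive"` or `"Model"`.
#' @return A two-row check-result data frame (I3-01 and I3-02 on the
#'   target).
#' @export
check_references <- function(metadata, target = c("Archive", "Model")) {
  target <- match.arg(target)
  id1 <- derive_target_id("I3-01", target)
  id2 <- derive_target_id("I3-02", target)
  refs <- metadata$references
  if (nrow(refs) == 0L) {
    return(rbind(
      .check_result(id1, "0", "metadata includes no references to other data"),
      .check_result(id2, "0",
        paste0("no references at all, so no qualified references either ",
               "(entailed by ", id1, " = 0)"))))
  }
  qualified <- refs[!is.na(refs$predicate), , drop = FALSE]
  rbind(
    .check_result(id1, "1", "metadata includes references to other data",
                  evidence = refs$target),
    if (nrow(qualified)) {
      .check_result(id2, "1",
        "at least one reference carries an explicit relation predicate",
        evidence = paste0(qualified$predicate, " -> ", qualified$target))
    } else {
      .check_result(id2, "0",
        "references exist but none carries an explicit relation predicate",
        evidence = refs$target)
    })
}

#' Check machine-understandable cross-community metadata
#'
#' Fulfilled when a separate metadata file exists, parses as RDF, and uses
#' at least one recognized cross-community vocabulary (Dublin Core, PROV,
#' FOAF, vCard, RDFS); partial (0.5) when the RDF parses but uses only
#' community-internal vocabularies; 0 otherwise.
#'
#' @param metadata A `metadata_record`.
#' @param target `"ModelMetadata"` or `"ArchiveMetadata"`.
#' @return A one-row check-result data frame for the R1.3-03 indicator on
#'   the target.
#' @export
check_cross_community_metadata <- function(metadata,
                                           target = c("ModelMetadata",
                                                      "ArchiveMetadata")) {
  target <- match.arg(target)
  id <- derive_target_id("R1.3-03", target)
  if (!metadata$has_separate_metadata_file ||
      length(metadata$parse_errors) > 0L) {
    return(.check_result(id, "0",
      "no separate machine-understandable metadata file (missing or unparseable)"))
  }
  recognized <- intersect(metadata$vocab_namespaces, .cross_community_ns)
  if (length(recognized)) {
    return(.check_result(id, "1",
      "metadata file uses recognized cross-community vocabulary terms",
      evidence = recognized))
  }
  if (length(metadata$vocab_namespaces)) {
    return(.check_result(id, "0.5",
      "metadata parses as RDF but uses only community-internal vocabularies",
      evidence = metadata$vocab_namespaces))
  }
  .check_result(id, "0", "metadata file carries no vocabulary statements")
}

#' Run every automatic check on an archive
#'
#' @param archive A `combine_archive`.
#' @param context A [repository_context()].
#' @return A check-result data frame, one row per proposed score.
#' @export
run_all_checks <- function(archive, context = repository_context("none")) {
  md <- archive$metadata
  rbind(
    check_standard_format(archive, "Model"),
    check_standard_format(archive, "Archive"),
    check_separate_metadata(archive, "ModelMetadata", context),
    check_separate_metadata(archive, "ArchiveMetadata", context),
    check_provenance(md, context, "ModelMetadata"),
    check_provenance(md, context, "ArchiveMetadata"),
    check_identifiers(archive, md, context),
    check_access_protocol(context),
    check_license(md, context),
    check_references(md, "Archive"),
    check_cross_community_metadata(md, "ModelMetadata"),
    check_cross_community_metadata(md, "ArchiveMetadata"))
}
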