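# Repository-context declarations.
#
# Some indicators depend on where a resource is hosted rather than on its
# bytes: a repository may expose an API and a free access protocol, assign
# persistent identifiers, carry a repository-wide licence agreed to by all
# hosted models, or hold standardized provenance on its record pages. The
# context declaration makes those capabilities available to the checks
# without any network access.

#' Declare the repository context of an assessment
#'
#' @param name One of `"BioModels-like"`, `"PMR-like"`, `"none"`,
#'   `"custom"`. The two repository presets fill the capability flags with
#'   typical values; `"none"` forces all capabilities off.
#' @param has_api_access Does the repository provide programmatic (API)
#'   access to the resource?
#' @param has_free_protocol Is the resource reachable through a free, open
#'   access protocol (e.g. plain HTTPS)?
#' @param repository_license Repository-wide licence URI/label that applies
#'   to all hosted resources, or `NA`.
#' @param assigns_persistent_ids Does the repository mint persistent
#'   identifiers (accessions) for hosted resources?
#' @param provides_provenance Does the repository record standardized
#'   provenance (submitter, dates, version history) on its record pages?
#' @return A `repository_context` list.
#' @examples
#' repository_context("BioModels-like")
#' repository_context("none")
#' @export
repository_context <- function(name = c("none", "BioModels-like", "PMR-like",
                                        "custom"),
                               has_api_access = NULL,
                               has_free_protocol = NULL,
                               repository_license = NULL,
                               assigns_persistent_ids = NULL,
                               provides_provenance = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    "BioModels-like" = list(has_api_access = TRUE, has_free_protocol = TRUE,
                            repository_license = "CC0",
                            assigns_persistent_ids = TRUE,
                            provides_provenance = TRUE),
    "PMR-like" = list(has_api_access = TRUE, has_free_protocol = TRUE,
                      repository_license = NA_character_,
                      assigns_persistent_ids = TRUE,
                      provides_provenance = TRUE),
    list(has_api_access = FALSE, has_free_protocol = FALSE,
         repository_license = NA_character_,
         assigns_persistent_ids = FALSE, provides_provenance = FALSE))
  ctx <- list(
    name = name,
    has_api_access = if (is.null(has_api_access)) defaults$has_api_access
                     else isTRUE(has_api_access),
    has_free_protocol = if (is.null(has_free_protocol)) {
      defaults$has_free_protocol
    } else {
      isTRUE(has_free_protocol)
    },
    repository_license = if (is.null(repository_license)) {
      defaults$repository_license
    } else {
      as.character(repository_license)
    },
    assigns_persistent_ids = if (is.null(assigns_persistent_ids)) {
      defaults$assigns_persistent_ids
    } else {
      isTRUE(assigns_persistent_ids)
    },
    provides_provenance = if (is.null(provides_provenance)) {
      defaults$provides_provenance
    } else {
      isTRUE(provides_provenance)
    })
  if (name == "none") {
    ctx$has_api_access <- FALSE
    ctx$has_free_protocol <- FALSE
    ctx$repository_license <- NA_character_
    ctx$assigns_persistent_ids <- FALSE
    ctx$provides_provenance <- FALSE
  }
  structure(ctx, class = "repository_context")
}

#' Read a repository-context declaration from a key-value file
#'
#' The file is plain `key = value` (or `key: value`) text with the fields
#' of [repository_context()]; unknown keys are rejected.
#'
#' @param path Path to the declaration file.
#' @return A `repository_context`.
#' @export
read_repository_context <- function(path) {
  if (!file.exists(path)) stop("context file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) == 0L]
  if (length(bad)) stop("malformed context line(s): ",
                        paste(bad, collapse = "; "), call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  allowed <- c("name", "has_api_access", "has_free_protocol",
               "repository_license", "assigns_persistent_ids",
               "provides_provenance")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown context key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  args <- as.list(vals)
  names(args) <- keys
  for (k in setdiff(keys, c("name", "repository_license"))) {
    args[[k]] <- tolower(args[[k]]) %in% c("true", "yes", "1")
  }
  do.call(repository_context, args)
}
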