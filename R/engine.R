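# Assessment orchestration: run checks, merge manual scores, propagate
# dependencies to a fixed point, validate and finalize.

#' Default indicator dependency rules
#'
#' Rules are data, not code: a table of (antecedent, dependent) indicator
#' pairs where assessing the antecedent as non-fulfilled (score 0) logically
#' entails that the dependent is non-fulfilled too. The shipped default
#' holds only entailment-justified pairs — the references/qualified-
#' references pairs on both resource sides and their metadata analogues.
#'
#' @param path Optional path to a custom rule table (tab-separated with
#'   columns `antecedent`, `dependent`, `trigger`, `forced`).
#' @return A data frame of dependency rules.
#' @export
default_dependency_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dependency_rules.tsv",
                        package = "faircombine", mustWork = TRUE)
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  required <- c("antecedent", "dependent", "trigger", "forced")
  if (!all(required %in% names(rules))) {
    stop("dependency rule table must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  bad <- rules$antecedent == rules$dependent
  if (any(bad)) {
    stop("self-dependency in rule table: ",
         paste(rules$antecedent[bad], collapse = ", "), call. = FALSE)
  }
  rules
}

# blank score map covering the registry
.blank_scores <- function(registry) {
  data.frame(indicator_id = registry$id,
             value = "PENDING",
             provenance = "pending",
             note = "",
             stringsAsFactors = FALSE)
}

.set_score <- function(scores, id, value, provenance, note = "") {
  i <- match(id, scores$indicator_id)
  stopifnot(!is.na(i))
  scores$value[i] <- value
  scores$provenance[i] <- provenance
  scores$note[i] <- note
  scores
}

#' Read a manual-score table
#'
#' Delimited text with columns `indicator_id`, `score`, `note`; score
#' tokens are `"0"`, `"0.5"`, `"1"`, `"NA"`.
#'
#' @param path Path to the table (tab- or comma-separated).
#' @return A data frame with character columns.
#' @export
read_manual_scores <- function(path) {
  if (!file.exists(path)) stop("manual-score file not found: ", path,
                               call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character",
                         quote = "\"", comment.char = "#")
  if (!all(c("indicator_id", "score") %in% names(m))) {
    stop("manual-score table must have columns indicator_id, score",
         call. = FALSE)
  }
  if (is.null(m$note)) m$note <- ""
  m$note[is.na(m$note)] <- ""
  m
}

.validate_manual <- function(manual, registry) {
  if (is.null(manual) || nrow(manual) == 0L) {
    return(data.frame(indicator_id = character(), score = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  manual$score <- trimws(as.character(manual$score))
  dup <- manual$indicator_id[duplicated(manual$indicator_id)]
  if (length(dup)) {
    stop("duplicate manual entries for indicator(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(manual$indicator_id, registry$id)
  if (length(unknown)) {
    stop("manual-score table references unknown indicator ID(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- !manual$score %in% c("0", "0.5", "1", "NA")
  if (any(bad)) {
    stop("manual score outside the allowed set {0, 0.5, 1, NA}: ",
         paste(unique(manual$score[bad]), collapse = ", "), call. = FALSE)
  }
  no_note <- manual$score == "0.5" & !nzchar(trimws(manual$note))
  if (any(no_note)) {
    stop("manual 0.5 score requires a justification note (indicator ",
         paste(manual$indicator_id[no_note], collapse = ", "), ")",
         call. = FALSE)
  }
  manual
}

#' Merge automatic check proposals with manual scores
#'
#' Manual values override automatic proposals; the provenance records the
#' winning source, and an overridden automatic proposal is retained in the
#' note as evidence.
#'
#' @param auto Check-result data frame (e.g. from [run_all_checks()]).
#' @param manual Manual-score data frame (`indicator_id`, `score`, `note`),
#'   or `NULL`.
#' @param registry A `fair_registry` (defines the score-map key set).
#' @return A score-map data frame (`indicator_id`, `value`, `provenance`,
#'   `note`) covering every registry indicator.
#' @export
merge_scores <- function(auto, manual = NULL, registry = load_registry()) {
  scores <- .blank_scores(registry)
  if (!is.null(auto) && nrow(auto)) {
    unknown <- setdiff(auto$indicator_id, registry$id)
    if (length(unknown)) {
      stop("check result references unknown indicator ID(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(auto))) {
      if (auto$proposed_score[i] == "PENDING") {
        scores <- .set_score(scores, auto$indicator_id[i], "PENDING",
                             "pending", auto$rationale[i])
      } else {
        prov <- if (!is.null(auto$provenance)) auto$provenance[i]
                else "automatic"
        scores <- .set_score(scores, auto$indicator_id[i],
                             auto$proposed_score[i], prov, auto$rationale[i])
      }
    }
  }
  manual <- .validate_manual(manual, registry)
  for (i in seq_len(nrow(manual))) {
    id <- manual$indicator_id[i]
    j <- match(id, scores$indicator_id)
    prior <- if (scores$provenance[j] %in% c("automatic",
                                             "repository-default")) {
      paste0(" [automatic proposal was ", scores$value[j], "]")
    } else {
      ""
    }
    scores <- .set_score(scores, id, manual$score[i], "manual",
                         paste0(manual$note[i], prior))
  }
  scores
}

#' Propagate dependency rules to a fixed point
#'
#' Applies each rule — antecedent assessed 0 forces the dependent to 0 —
#' iteratively until nothing changes. Propagation never raises a score: a
#' dependent already 0 is untouched, an NA (not-applicable) dependent is
#' skipped, and manual scores can only be overwritten downward (non-zero
#' to 0), never upward.
#'
#' @param scores A score-map data frame.
#' @param rules A dependency-rule data frame (see
#'   [default_dependency_rules()]). Must be acyclic.
#' @return The score map at the fixed point.
#' @export
propagate_dependencies <- function(scores, rules = default_dependency_rules()) {
  if (is.null(rules) || nrow(rules) == 0L) return(scores)
  .assert_acyclic(rules)
  rules <- rules[rules$antecedent %in% scores$indicator_id &
                   rules$dependent %in% scores$indicator_id, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(rules))) {
      a <- match(rules$antecedent[i], scores$indicator_id)
      d <- match(rules$dependent[i], scores$indicator_id)
      if (scores$value[a] == rules$trigger[i] &&
          !scores$value[d] %in% c(rules$forced[i], "NA")) {
        scores$value[d] <- rules$forced[i]
        scores$provenance[d] <- "propagated"
        scores$note[d] <- paste0("forced to ", rules$forced[i], " because ",
                                 rules$antecedent[i], " = ",
                                 rules$trigger[i])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  scores
}

.assert_acyclic <- function(rules) {
  # Kahn's algorithm on the antecedent -> dependent graph
  nodes <- unique(c(rules$antecedent, rules$dependent))
  edges <- rules[, c("antecedent", "dependent")]
  indeg <- vapply(nodes, function(n) sum(edges$dependent == n), integer(1))
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    outs <- edges$dependent[edges$antecedent == n]
    for (m in outs) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) queue <- c(queue, m)
    }
    edges <- edges[edges$antecedent != n, , drop = FALSE]
  }
  if (seen != length(nodes)) {
    stop("dependency rule table contains a cycle", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a full semi-automatic assessment
#'
#' Executes every automatic check on the archive, merges manual scores
#' (manual overrides automatic), propagates dependency rules to a fixed
#' point, and returns a draft assessment covering every registry
#' indicator. For a bare model file (single-entry pseudo-archive) the
#' archive-side indicators are scored not-applicable. Indicators no check
#' or manual entry covers remain `PENDING` until [finalize_assessment()].
#'
#' @param archive A `combine_archive` from [read_archive()].
#' @param registry A `fair_registry`.
#' @param context A [repository_context()].
#' @param manual Manual-score data frame or path to a manual-score file,
#'   or `NULL`.
#' @param rules Dependency-rule data frame.
#' @return A `fair_assessment`: list with `scores`, `subject`, `context`,
#'   `registry_version`, `finalized`.
#' @examples
#' \dontrun{
#' arch <- read_archive(make_archive(list_presets()[[1]], tempfile()))
#' a <- run_assessment(arch, context = repository_context("BioModels-like"))
#' }
#' @export
run_assessment <- function(archive, registry = load_registry(),
                           context = repository_context("none"),
                           manual = NULL,
                           rules = default_dependency_rules()) {
  stopifnot(inherits(archive, "combine_archive"),
            inherits(registry, "fair_registry"))
  if (is.character(manual)) manual <- read_manual_scores(manual)
  auto <- run_all_checks(archive, context)
  if (isTRUE(archive$bare)) {
    # archive-target indicators are not applicable to a bare model file
    arch_ids <- registry$id[registry$target %in% c("Archive",
                                                   "ArchiveMetadata")]
    auto <- auto[!auto$indicator_id %in% arch_ids, , drop = FALSE]
    na_rows <- do.call(rbind, lapply(arch_ids, function(id) {
      .check_result(id, "NA",
        "bare model file: archive-side indicators are not applicable")
    }))
    auto <- rbind(auto, na_rows)
  }
  scores <- merge_scores(auto, manual, registry)
  scores <- propagate_dependencies(scores, rules)
  structure(list(scores = scores,
                 subject = archive$source_path,
                 context = context,
                 registry_version = registry_version(registry),
                 finalized = FALSE),
            class = "fair_assessment")
}

#' Validate an assessment
#'
#' Report-only completeness check: missing or extraneous indicators,
#' remaining `PENDING` scores, and manual 0.5 scores lacking a
#' justification note. A finalized assessment must report zero defects.
#'
#' @param assessment A `fair_assessment`.
#' @param registry A `fair_registry`.
#' @return A data frame of defects (`defect`, `indicator_id`, `message`);
#'   zero rows when the assessment is complete.
#' @export
validate_assessment <- function(assessment, registry = load_registry()) {
  stopifnot(inherits(assessment, "fair_assessment"))
  s <- assessment$scores
  defects <- data.frame(defect = character(), indicator_id = character(),
                        message = character(), stringsAsFactors = FALSE)
  add <- function(defect, id, msg) {
    rbind(defects, data.frame(defect = defect, indicator_id = id,
                              message = msg, stringsAsFactors = FALSE))
  }
  for (id in setdiff(registry$id, s$indicator_id)) {
    defects <- add("missing_indicator", id,
                   "registry indicator absent from the score map")
  }
  for (id in setdiff(s$indicator_id, registry$id)) {
    defects <- add("unknown_indicator", id,
                   "score map entry not in the registry")
  }
  pend <- s$indicator_id[s$value == "PENDING"]
  for (id in pend) {
    defects <- add("pending", id, "indicator still awaiting a score")
  }
  half <- s$value == "0.5" & s$provenance == "manual" & !nzchar(trimws(s$note))
  for (id in s$indicator_id[half]) {
    defects <- add("half_score_without_note", id,
                   "manual 0.5 score lacks the mandatory justification note")
  }
  defects
}

#' Finalize an assessment
#'
#' A finalized assessment may contain no `PENDING` scores. By default any
#' remaining pending indicator is an error; alternatively pending scores
#' can be filled with 0 (conservative: unassessed treated as
#' non-fulfilled) or NA (excluded from aggregation).
#'
#' @param assessment A `fair_assessment`.
#' @param pending One of `"error"`, `"zero"`, `"na"`.
#' @param registry A `fair_registry` used for the final validation.
#' @return The finalized `fair_assessment`.
#' @export
finalize_assessment <- function(assessment,
                                pending = c("error", "zero", "na"),
                                registry = load_registry()) {
  pending <- match.arg(pending)
  s <- assessment$scores
  idx <- which(s$value == "PENDING")
  if (length(idx)) {
    if (pending == "error") {
      stop("cannot finalize: ", length(idx),
           " indicator(s) still pending: ",
           paste(utils::head(s$indicator_id[idx], 5L), collapse = ", "),
           if (length(idx) > 5L) ", ...", call. = FALSE)
    }
    fill <- if (pending == "zero") "0" else "NA"
    s$value[idx] <- fill
    s$provenance[idx] <- "manual"
    s$note[idx] <- paste0("unresolved at finalization; recorded as ", fill)
  }
  assessment$scores <- s
  assessment$finalized <- TRUE
  defects <- validate_assessment(assessment, registry)
  if (nrow(defects)) {
    stop("finalized assessment still has ", nrow(defects), " defect(s); ",
         "first: ", defects$defect[1], " (", defects$indicator_id[1], ")",
         call. = FALSE)
  }
  assessment
}

#' @export
print.fair_assessment <- function(x, ...) {
  s <- x$scores
  cat("FAIR assessment of:", x$subject, "\n")
  cat(" registry:", x$registry_version,
      "| context:", x$context$name,
      "| finalized:", x$finalized, "\n")
  print(table(value = s$value, provenance = s$provenance))
  invisible(x)
}

# numeric view of score tokens (NA for "NA" and "PENDING")
.score_numeric <- function(value) {
  out <- suppressWarnings(as.numeric(value))
  out[value %in% c("NA", "PENDING")] <- NA_real_
  out
}
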