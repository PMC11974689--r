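# Aggregation of finalized assessments into FAIRness summaries, chart-row
# export (radial-column-chart data), and report writing/reading.

.fc_colors <- c(F = "blue", A = "orange", I = "green", R = "red")

#' Aggregate an assessment into FAIRness percentages
#'
#' Each slice percentage is `100 * sum(numeric scores) / (number of non-NA
#' indicators in the slice)`; not-applicable indicators are excluded from
#' every denominator, and a slice that is entirely not-applicable is
#' reported as `NA`. The overall percentage is the same statistic over all
#' non-NA indicators (equivalently, the non-NA-count-weighted mean of the
#' per-target percentages).
#'
#' @param assessment A finalized `fair_assessment`.
#' @param registry A `fair_registry`.
#' @return A `score_summary`: list with `by_principle` (percent per F, A,
#'   I, R), `by_target` (percent per assessment target), `by_priority`
#'   (fraction fulfilled per priority level), `counts`
#'   (`n_scored`, `n_na`, `n_half`), and `overall` (percent).
#' @export
aggregate_scores <- function(assessment, registry = load_registry()) {
  stopifnot(inherits(assessment, "fair_assessment"))
  if (!isTRUE(assessment$finalized)) {
    stop("assessment must be finalized before aggregation ",
         "(see finalize_assessment())", call. = FALSE)
  }
  s <- assessment$scores
  ord <- match(registry$id, s$indicator_id)
  stopifnot(!anyNA(ord))
  s <- s[ord, ]
  num <- .score_numeric(s$value)
  letter <- substr(registry$principle, 1, 1)
  pct <- function(v) {
    keep <- !is.na(v)
    if (!any(keep)) return(NA_real_)
    100 * sum(v[keep]) / sum(keep)
  }
  by_principle <- vapply(c("F", "A", "I", "R"),
                         function(p) pct(num[letter == p]), numeric(1))
  targets <- c("Model", "ModelMetadata", "Archive", "ArchiveMetadata")
  by_target <- vapply(targets,
                      function(tg) pct(num[registry$target == tg]),
                      numeric(1))
  by_priority <- vapply(.fc_priorities, function(pr) {
    v <- num[registry$priority == pr]
    keep <- !is.na(v)
    if (!any(keep)) return(NA_real_)
    sum(v[keep]) / sum(keep)
  }, numeric(1))
  structure(list(
    by_principle = by_principle,
    by_target = by_target,
    by_priority = by_priority,
    counts = c(n_scored = sum(!is.na(num)), n_na = sum(is.na(num)),
               n_half = sum(s$value == "0.5")),
    overall = pct(num)
  ), class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat("FAIRness summary\n overall:",
      if (is.na(x$overall)) "NA" else sprintf("%.1f%%", x$overall), "\n")
  cat(" by principle:",
      paste(names(x$by_principle),
            sprintf("%.1f%%", x$by_principle), collapse = " | "), "\n")
  cat(" by target:",
      paste(names(x$by_target),
            ifelse(is.na(x$by_target), "NA",
                   sprintf("%.1f%%", x$by_target)), collapse = " | "), "\n")
  cat(" scored:", x$counts[["n_scored"]], "| NA:", x$counts[["n_na"]],
      "| partial (0.5):", x$counts[["n_half"]], "\n")
  invisible(x)
}

#' Export radial-column-chart rows
#'
#' One row per indicator, grouped by target panel (Model, Model metadata,
#' Archive, Archive metadata), ordered F, A, I, R then by sub-principle and
#' ordinal. The colour key follows the FAIR convention: Findability blue,
#' Accessibility orange, Interoperability green, Reusability red.
#' Not-applicable indicators keep their row with an `NA` score (no column
#' height).
#'
#' @param assessment A finalized `fair_assessment`.
#' @param registry A `fair_registry`.
#' @return A data frame with columns `indicator_id`, `principle`,
#'   `principle_group`, `target`, `score`, `color`.
#' @export
export_chart_data <- function(assessment, registry = load_registry()) {
  stopifnot(inherits(assessment, "fair_assessment"))
  if (!isTRUE(assessment$finalized)) {
    stop("assessment must be finalized before chart export", call. = FALSE)
  }
  s <- assessment$scores
  reg <- as.data.frame(registry, stringsAsFactors = FALSE)
  reg$letter <- substr(reg$principle, 1, 1)
  reg$score <- .score_numeric(s$value[match(reg$id, s$indicator_id)])
  target_order <- c("Model", "ModelMetadata", "Archive", "ArchiveMetadata")
  reg <- reg[order(match(reg$target, target_order),
                   match(reg$letter, c("F", "A", "I", "R")),
                   reg$principle, reg$ordinal), ]
  data.frame(indicator_id = reg$id,
             principle = reg$principle,
             principle_group = reg$letter,
             target = reg$target,
             score = reg$score,
             color = unname(.fc_colors[reg$letter]),
             stringsAsFactors = FALSE, row.names = NULL)
}

.summary_to_list <- function(s) {
  list(by_principle = as.list(s$by_principle),
       by_target = as.list(s$by_target),
       by_priority = as.list(s$by_priority),
       counts = as.list(s$counts),
       overall = s$overall)
}

#' Write an assessment report
#'
#' Structured JSON retains every indicator's score, provenance and note
#' plus the summary and context, and round-trips exactly through
#' [read_report()]. CSV writes the per-indicator score table; markdown
#' writes a human-readable report (with a defects section while drafting).
#' Output is deterministic: two writes of the same assessment are
#' byte-identical.
#'
#' @param assessment A `fair_assessment`.
#' @param summary A `score_summary`, or `NULL` to omit (required for
#'   finalized JSON/markdown reports it is computed on the fly when a
#'   registry is supplied).
#' @param format One of `"json"`, `"csv"`, `"markdown"`.
#' @param destination Output file path.
#' @param registry A `fair_registry` (used to compute the summary when
#'   `summary` is `NULL` and the assessment is finalized).
#' @return `destination`, invisibly.
#' @export
write_report <- function(assessment, summary = NULL,
                         format = c("json", "csv", "markdown"),
                         destination, registry = load_registry()) {
  format <- match.arg(format)
  stopifnot(inherits(assessment, "fair_assessment"))
  if (is.null(summary) && isTRUE(assessment$finalized)) {
    summary <- aggregate_scores(assessment, registry)
  }
  s <- assessment$scores
  if (format == "json") {
    payload <- list(
      subject = assessment$subject,
      registry_version = assessment$registry_version,
      finalized = assessment$finalized,
      context = unclass(assessment$context),
      scores = lapply(seq_len(nrow(s)), function(i) {
        list(indicator_id = s$indicator_id[i], value = s$value[i],
             provenance = s$provenance[i], note = s$note[i])
      }),
      summary = if (!is.null(summary)) .summary_to_list(summary))
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                             na = "null", digits = NA, pretty = TRUE)
    writeLines(json, destination)
  } else if (format == "csv") {
    utils::write.csv(s, destination, row.names = FALSE, quote = TRUE)
  } else {
    defects <- validate_assessment(assessment, registry)
    lines <- c(
      paste0("# FAIR assessment report"),
      "",
      paste0("- Subject: ", assessment$subject),
      paste0("- Repository context: ", assessment$context$name),
      paste0("- Registry version: ", assessment$registry_version),
      paste0("- Status: ",
             if (assessment$finalized) "finalized" else "draft"),
      "")
    if (!is.null(summary)) {
      lines <- c(lines, "## FAIRness summary", "",
        paste0("- Overall: ", sprintf("%.1f%%", summary$overall)),
        paste0("- ", names(summary$by_principle), ": ",
               sprintf("%.1f%%", summary$by_principle)),
        "")
    }
    if (nrow(defects)) {
      lines <- c(lines, "## Open defects", "",
        paste0("- ", defects$defect, " ", defects$indicator_id, ": ",
               defects$message),
        "")
    }
    lines <- c(lines, "## Scores", "",
               "| indicator | score | provenance | note |",
               "| --- | --- | --- | --- |",
               sprintf("| %s | %s | %s | %s |", s$indicator_id, s$value,
                       s$provenance, gsub("\\|", "/", s$note)))
    writeLines(lines, destination)
  }
  invisible(destination)
}

#' Read a structured JSON report back into an assessment
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The `fair_assessment` reconstructed from the report.
#' @export
read_report <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  scores <- do.call(rbind, lapply(payload$scores, function(r) {
    data.frame(indicator_id = r$indicator_id, value = r$value,
               provenance = r$provenance,
               note = if (is.null(r$note)) "" else r$note,
               stringsAsFactors = FALSE)
  }))
  ctx <- payload$context
  context <- repository_context(
    name = ctx$name,
    has_api_access = isTRUE(ctx$has_api_access),
    has_free_protocol = isTRUE(ctx$has_free_protocol),
    repository_license = if (is.null(ctx$repository_license)) NA_character_
                         else ctx$repository_license,
    assigns_persistent_ids = isTRUE(ctx$assigns_persistent_ids),
    provides_provenance = isTRUE(ctx$provides_provenance))
  structure(list(scores = scores,
                 subject = payload$subject,
                 context = context,
                 registry_version = payload$registry_version,
                 finalized = isTRUE(payload$finalized)),
            class = "fair_assessment")
}
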