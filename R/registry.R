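# Valid target names and their indicator-ID suffixes.
.fc_targets <- c(Model = "Model", ModelMetadata = "MM",
                 Archive = "Archive", ArchiveMetadata = "MA")
.fc_priorities <- c("Essential", "Important", "Useful")
.fc_modes <- c("automatic", "manual", "hybrid")

#' Path to the default COMBINE FAIR indicator registry file
#'
#' @return Path to the tab-separated registry data file shipped with the
#'   package (one row per indicator).
#' @export
default_registry_file <- function() {
  system.file("extdata", "combine_fair_indicators.tsv",
              package = "faircombine", mustWork = TRUE)
}

#' Load the COMBINE-adapted RDA FAIR indicator registry
#'
#' Reads and validates the registry of FAIR maturity indicators adapted to
#' COMBINE resources. The registry distinguishes four assessment targets:
#' the model itself (`Model`), its metadata (`ModelMetadata`, ID suffix
#' `MM`), the COMBINE archive (`Archive`), and the archive metadata
#' (`ArchiveMetadata`, suffix `MA`). The default registry holds 84
#' indicators: each of the 41 RDA base indicators in one model-side and one
#' archive-side variant, plus two COMBINE-specific cross-community metadata
#' indicators (`CA-RDA-R1.3-03MM`, `CA-RDA-R1.3-03MA`).
#'
#' Any violation of the structural invariants (84 total, 42 per side,
#' unique IDs, exactly three priority levels, exactly two COMBINE-new
#' indicators, ID grammar consistent with the declared target) is a load
#' error, not a warning.
#'
#' @param source Path to a registry data file (tab-separated, one row per
#'   indicator with columns `id`, `principle`, `ordinal`, `target`,
#'   `priority`, `description`, `assessment_mode`, `origin`). Defaults to
#'   the registry shipped with the package.
#' @return A `fair_registry` object: a data frame of indicators with a
#'   `version` attribute.
#' @examples
#' reg <- load_registry()
#' nrow(reg)  # 84
#' @export
load_registry <- function(source = default_registry_file()) {
  if (!file.exists(source)) {
    stop("registry file not found: ", source, call. = FALSE)
  }
  first <- readLines(source, n = 1L)
  version <- if (grepl("^#\\s*registry_version:", first)) {
    trimws(sub("^#\\s*registry_version:", "", first))
  } else {
    "unversioned"
  }
  reg <- utils::read.delim(source, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  required <- c("id", "principle", "ordinal", "target", "priority",
                "description", "assessment_mode", "origin")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols)) {
    stop("registry file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(reg) == 0L) {
    stop("registry load failed: no indicators in ", source, call. = FALSE)
  }
  reg$ordinal <- formatC(as.integer(reg$ordinal), width = 2, flag = "0")
  .validate_registry(reg)
  structure(reg, class = c("fair_registry", "data.frame"), version = version)
}

.validate_registry <- function(reg) {
  fail <- function(...) stop("registry invariant violated: ", ...,
                             call. = FALSE)
  dup <- reg$id[duplicated(reg$id)]
  if (length(dup)) fail("duplicated IDs: ", paste(unique(dup), collapse = ", "))
  bad_target <- setdiff(unique(reg$target), names(.fc_targets))
  if (length(bad_target)) fail("unknown target(s): ",
                               paste(bad_target, collapse = ", "))
  # every ID must parse and agree with its declared fields
  for (i in seq_len(nrow(reg))) {
    p <- tryCatch(parse_indicator_id(reg$id[i]), error = function(e) e)
    if (inherits(p, "error")) fail("unparseable ID ", reg$id[i])
    if (p$target != reg$target[i]) {
      fail("ID ", reg$id[i], " suffix disagrees with declared target ",
           reg$target[i])
    }
    if (p$principle != reg$principle[i] || p$ordinal != reg$ordinal[i]) {
      fail("ID ", reg$id[i], " disagrees with declared principle/ordinal")
    }
  }
  if (nrow(reg) != 84L) fail("expected 84 indicators, found ", nrow(reg))
  n_model_side <- sum(reg$target %in% c("Model", "ModelMetadata"))
  n_archive_side <- sum(reg$target %in% c("Archive", "ArchiveMetadata"))
  if (n_model_side != 42L) fail("expected 42 model-side indicators, found ",
                                n_model_side)
  if (n_archive_side != 42L) fail("expected 42 archive-side indicators, found ",
                                  n_archive_side)
  bad_prio <- setdiff(unique(reg$priority), .fc_priorities)
  if (length(bad_prio)) fail("unknown priority value(s): ",
                             paste(bad_prio, collapse = ", "))
  if (length(unique(reg$priority)) != 3L) {
    fail("expected exactly 3 priority levels, found ",
         length(unique(reg$priority)))
  }
  new_ids <- sort(reg$id[reg$origin == "combine_new"])
  if (!identical(new_ids, c("CA-RDA-R1.3-03MA", "CA-RDA-R1.3-03MM"))) {
    fail("combine_new must be exactly CA-RDA-R1.3-03MM and CA-RDA-R1.3-03MA, ",
         "found: ", paste(new_ids, collapse = ", "))
  }
  bad_mode <- setdiff(unique(reg$assessment_mode), .fc_modes)
  if (length(bad_mode)) fail("unknown assessment_mode(s): ",
                             paste(bad_mode, collapse = ", "))
  # every base indicator exists once per side under the same base code
  base <- reg[reg$origin == "rda_base", ]
  key <- paste0(base$principle, "-", base$ordinal,
                ifelse(base$target %in% c("Model", "Archive"), ":data", ":meta"))
  side <- ifelse(base$target %in% c("Model", "ModelMetadata"),
                 "model", "archive")
  tab <- table(key, side)
  if (any(tab != 1L)) {
    off <- rownames(tab)[apply(tab != 1L, 1, any)]
    fail("base indicator(s) not present exactly once per side: ",
         paste(off, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.fair_registry <- function(x, ...) {
  cat("COMBINE FAIR indicator registry (version ",
      attr(x, "version"), ")\n", sep = "")
  cat(nrow(x), "indicators;",
      sum(x$target %in% c("Model", "ModelMetadata")), "model-side,",
      sum(x$target %in% c("Archive", "ArchiveMetadata")), "archive-side\n")
  print(table(principle = substr(x$principle, 1, 1), priority = x$priority))
  invisible(x)
}

#' Look up one indicator by its ID
#'
#' @param registry A `fair_registry` from [load_registry()].
#' @param id Indicator ID string, e.g. `"CA-RDA-R1.3-03MM"`.
#' @return A one-row data frame (the indicator record).
#' @examples
#' reg <- load_registry()
#' lookup_indicator(reg, "CA-RDA-I3-02Archive")$description
#' @export
lookup_indicator <- function(registry, id) {
  stopifnot(inherits(registry, "fair_registry"), is.character(id),
            length(id) == 1L)
  hit <- registry[registry$id == id, , drop = FALSE]
  if (nrow(hit) == 0L) {
    d <- utils::adist(id, registry$id)
    near <- registry$id[order(d)][seq_len(3L)]
    stop("unknown indicator ID '", id, "'; nearest matches: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  as.data.frame(hit, stringsAsFactors = FALSE)
}

#' Parse an indicator ID into its components
#'
#' Indicator IDs follow the grammar
#' `"CA-RDA-" principle "-" ordinal suffix` where `principle` is a FAIR
#' letter plus sub-principle (e.g. `A1.1`), `ordinal` is two digits, and
#' the suffix is one of `Model`, `MM`, `Archive`, `MA`.
#'
#' @param id Indicator ID string.
#' @return A list with elements `principle`, `ordinal`, `target`.
#' @examples
#' parse_indicator_id("CA-RDA-A1.1-01Model")
#' @export
parse_indicator_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  rx <- "^CA-RDA-([FAIR][0-9](?:\\.[0-9])?)-([0-9]{2})(Model|MM|Archive|MA)$"
  m <- regmatches(id, regexec(rx, id))[[1]]
  if (length(m) == 0L) {
    # locate the first position where the ID stops matching the grammar
    stages <- c("^CA-RDA-", "^CA-RDA-[FAIR]", "^CA-RDA-[FAIR][0-9]",
                "^CA-RDA-[FAIR][0-9](\\.[0-9])?-",
                "^CA-RDA-[FAIR][0-9](\\.[0-9])?-[0-9]{2}")
    pos <- 1L
    for (s in stages) {
      mm <- regmatches(id, regexpr(s, id))
      if (length(mm) == 0L) break
      pos <- nchar(mm) + 1L
    }
    stop("malformed indicator ID '", id,
         "': does not match the CA-RDA grammar (parse fails near position ",
         pos, ")", call. = FALSE)
  }
  target <- names(.fc_targets)[match(m[4], .fc_targets)]
  list(principle = m[2], ordinal = m[3], target = target)
}

#' Build an indicator ID from a base code and a target
#'
#' Inverse of [parse_indicator_id()]: maps an RDA base code such as
#' `"R1.2-01"` plus an assessment target to the COMBINE-adapted ID.
#'
#' @param base_code RDA sub-principle plus ordinal, e.g. `"I3-01"`.
#' @param target One of `"Model"`, `"ModelMetadata"`, `"Archive"`,
#'   `"ArchiveMetadata"` (the ID suffixes `MM`/`MA` are also accepted).
#' @return The indicator ID string.
#' @examples
#' derive_target_id("R1.2-01", "ModelMetadata")  # "CA-RDA-R1.2-01MM"
#' @export
derive_target_id <- function(base_code, target) {
  stopifnot(is.character(base_code), length(base_code) == 1L,
            is.character(target), length(target) == 1L)
  if (!grepl("^[FAIR][0-9](\\.[0-9])?-[0-9]{2}$", base_code)) {
    stop("invalid base indicator code '", base_code,
         "' (expected e.g. 'R1.2-01')", call. = FALSE)
  }
  if (target %in% .fc_targets) {
    target <- names(.fc_targets)[match(target, .fc_targets)]
  }
  if (!target %in% names(.fc_targets)) {
    stop("invalid target '", target, "'; must be one of ",
         paste(names(.fc_targets), collapse = ", "), call. = FALSE)
  }
  paste0("CA-RDA-", base_code, .fc_targets[[target]])
}

#' @rdname load_registry
#' @param registry A `fair_registry`.
#' @return `registry_version()`: the version tag of a loaded registry.
#' @export
registry_version <- function(registry) {
  stopifnot(inherits(registry, "fair_registry"))
  attr(registry, "version")
}
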