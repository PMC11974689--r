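test_that("merge gives manual scores precedence over automatic proposals", {
  auto <- data.frame(
    indicator_id = c("CA-RDA-R1.3-01Model", "CA-RDA-I3-01Archive"),
    proposed_score = c("1", "0"),
    rationale = c("standard format", "no references"),
    evidence = "", provenance = "automatic", stringsAsFactors = FALSE)
  s <- merge_scores(auto, NULL, fc_registry)
  expect_equal(nrow(s), 84L)
  expect_equal(fc_get(s, "CA-RDA-R1.3-01Model"), "1")
  expect_equal(s$provenance[s$indicator_id == "CA-RDA-R1.3-01Model"],
               "automatic")
  # manual overrides; the automatic proposal stays in the note
  manual <- data.frame(indicator_id = "CA-RDA-I3-01Archive", score = "1",
                       note = "curator found a reference in the publication",
                       stringsAsFactors = FALSE)
  s2 <- merge_scores(auto, manual, fc_registry)
  expect_equal(fc_get(s2, "CA-RDA-I3-01Archive"), "1")
  expect_equal(s2$provenance[s2$indicator_id == "CA-RDA-I3-01Archive"],
               "manual")
  expect_match(s2$note[s2$indicator_id == "CA-RDA-I3-01Archive"],
               "automatic proposal was 0")
})

test_that("manual-score validation rejects malformed input", {
  bad_score <- data.frame(indicator_id = "CA-RDA-I3-01Archive",
                          score = "0.7", note = "", stringsAsFactors = FALSE)
  expect_error(merge_scores(NULL, bad_score, fc_registry),
               "outside the allowed set")
  unknown <- data.frame(indicator_id = "CA-RDA-Z9-99Model", score = "1",
                        note = "", stringsAsFactors = FALSE)
  expect_error(merge_scores(NULL, unknown, fc_registry), "unknown indicator")
  dup <- data.frame(indicator_id = rep("CA-RDA-I3-01Archive", 2),
                    score = c("1", "0"), note = "", stringsAsFactors = FALSE)
  expect_error(merge_scores(NULL, dup, fc_registry), "duplicate")
  half_no_note <- data.frame(indicator_id = "CA-RDA-I3-01Archive",
                             score = "0.5", note = "",
                             stringsAsFactors = FALSE)
  expect_error(merge_scores(NULL, half_no_note, fc_registry),
               "justification note")
})

test_that("a non-fulfilled antecedent forces its dependent to zero", {
  s <- fc_blank_scores()
  s <- fc_set(s, "CA-RDA-I3-01Archive", "0", "automatic", "no refs")
  out <- propagate_dependencies(s, default_dependency_rules())
  expect_equal(fc_get(out, "CA-RDA-I3-02Archive"), "0")
  expect_equal(out$provenance[out$indicator_id == "CA-RDA-I3-02Archive"],
               "propagated")
  # trigger not met: nothing changes
  s2 <- fc_blank_scores()
  s2 <- fc_set(s2, "CA-RDA-I3-01Archive", "1", "automatic", "refs")
  s2 <- fc_set(s2, "CA-RDA-I3-02Archive", "0", "automatic", "unqualified")
  out2 <- propagate_dependencies(s2, default_dependency_rules())
  expect_identical(out2, s2)
  # NA dependents are never forced
  s3 <- fc_blank_scores()
  s3 <- fc_set(s3, "CA-RDA-I3-01Archive", "0", "automatic", "no refs")
  s3 <- fc_set(s3, "CA-RDA-I3-02Archive", "NA", "manual", "not applicable")
  out3 <- propagate_dependencies(s3, default_dependency_rules())
  expect_equal(fc_get(out3, "CA-RDA-I3-02Archive"), "NA")
})

test_that("the default rule table covers both resource sides of the I3 pair", {
  rules <- default_dependency_rules()
  expect_true(any(rules$antecedent == "CA-RDA-I3-01Archive" &
                    rules$dependent == "CA-RDA-I3-02Archive"))
  expect_true(any(rules$antecedent == "CA-RDA-I3-01Model" &
                    rules$dependent == "CA-RDA-I3-02Model"))
  expect_true(all(rules$antecedent != rules$dependent))
  expect_true(all(c(rules$antecedent, rules$dependent) %in% fc_registry$id))
})

test_that("chains propagate to a fixed point and cycles are rejected", {
  chain <- data.frame(
    antecedent = c("CA-RDA-I3-01Archive", "CA-RDA-I3-02Archive"),
    dependent = c("CA-RDA-I3-02Archive", "CA-RDA-I3-03MA"),
    trigger = "0", forced = "0", stringsAsFactors = FALSE)
  s <- fc_blank_scores()
  s <- fc_set(s, "CA-RDA-I3-01Archive", "0", "automatic", "no refs")
  s <- fc_set(s, "CA-RDA-I3-02Archive", "1", "manual", "claimed")
  s <- fc_set(s, "CA-RDA-I3-03MA", "1", "manual", "claimed")
  out <- propagate_dependencies(s, chain)
  expect_equal(fc_get(out, "CA-RDA-I3-02Archive"), "0")
  expect_equal(fc_get(out, "CA-RDA-I3-03MA"), "0")
  cyc <- data.frame(antecedent = c("a", "b"), dependent = c("b", "a"),
                    trigger = "0", forced = "0", stringsAsFactors = FALSE)
  s2 <- data.frame(indicator_id = c("a", "b"), value = c("0", "1"),
                   provenance = "manual", note = "", stringsAsFactors = FALSE)
  expect_error(propagate_dependencies(s2, cyc), "cycle")
})

test_that("propagation is idempotent, monotone and convergent on random acyclic tables", {
  rank <- c("0" = 0, "0.5" = 0.5, "1" = 1, "NA" = NA_real_,
            "PENDING" = NA_real_)
  set.seed(424242)
  for (rep in seq_len(100L)) {
    ids <- sample(fc_registry$id)           # random topological order
    n_rules <- sample(5:25, 1L)
    from <- sample(seq_len(83L), n_rules, replace = TRUE)
    to <- vapply(from, function(f) f + sample.int(84L - f, 1L), integer(1))
    rules <- data.frame(antecedent = ids[from], dependent = ids[to],
                        trigger = "0", forced = "0",
                        stringsAsFactors = FALSE)
    rules <- rules[!duplicated(rules[c("antecedent", "dependent")]), ]
    s <- data.frame(
      indicator_id = fc_registry$id,
      value = sample(c("0", "0.5", "1", "NA", "PENDING"), 84L,
                     replace = TRUE),
      provenance = "manual", note = "n", stringsAsFactors = FALSE)
    out <- propagate_dependencies(s, rules)
    # idempotence
    expect_identical(propagate_dependencies(out, rules), out)
    # monotone non-increase on numeric scores
    before <- rank[s$value]
    after <- rank[out$value]
    changed <- s$value != out$value
    expect_true(all(out$value[changed] == "0"))
    num_both <- !is.na(before) & !is.na(after)
    expect_true(all(after[num_both] <= before[num_both]))
    # fixed point: no rule still fires (NA dependents exempt)
    for (i in seq_len(nrow(rules))) {
      a <- fc_get(out, rules$antecedent[i])
      d <- fc_get(out, rules$dependent[i])
      if (a == "0" && d != "NA") expect_equal(d, "0")
    }
  }
})

test_that("run_assessment composes checks, manual input and propagation", {
  a <- read_archive(fc_fixture("highly_curated_biomodels_like"))
  ass <- run_assessment(a, fc_registry,
                        repository_context("BioModels-like"))
  expect_s3_class(ass, "fair_assessment")
  expect_setequal(ass$scores$indicator_id, fc_registry$id)
  expect_equal(fc_get(ass$scores, "CA-RDA-R1.3-01Model"), "1")
  expect_equal(fc_get(ass$scores, "CA-RDA-A1-05Model"), "1")
  expect_equal(fc_get(ass$scores, "CA-RDA-A1.1-01Model"), "1")
  expect_equal(fc_get(ass$scores, "CA-RDA-R1.1-01MM"), "1")
  # empty pseudo-archive with no context: nothing scores 1
  path <- tempfile(fileext = ".zip")
  faircombine:::.write_zip(path, list(
    "model.txt" = "not a standard model"))
  empty <- read_archive(path)
  ass0 <- run_assessment(empty, fc_registry, repository_context("none"))
  expect_false(any(ass0$scores$value == "1"))
  expect_true(all(ass0$scores$value %in% c("0", "PENDING")))
  # invalid manual score token fails validation
  bad <- data.frame(indicator_id = "CA-RDA-I3-01Archive", score = "0.7",
                    note = "", stringsAsFactors = FALSE)
  expect_error(run_assessment(a, fc_registry,
                              repository_context("none"), manual = bad),
               "outside the allowed set")
})

test_that("bare model files score archive-side indicators not-applicable", {
  f <- tempfile(fileext = ".xml")
  writeLines(make_model_file("SBML", TRUE, 2L), f)
  ass <- run_assessment(read_archive(f), fc_registry,
                        repository_context("none"))
  arch_ids <- fc_registry$id[fc_registry$target %in%
                               c("Archive", "ArchiveMetadata")]
  expect_true(all(ass$scores$value[ass$scores$indicator_id %in%
                                     arch_ids] == "NA"))
  # manual NA on an archive-target indicator is preserved
  man <- data.frame(indicator_id = "CA-RDA-I3-01Archive", score = "NA",
                    note = "bare model", stringsAsFactors = FALSE)
  ass2 <- run_assessment(read_archive(f), fc_registry,
                         repository_context("none"), manual = man)
  expect_equal(fc_get(ass2$scores, "CA-RDA-I3-01Archive"), "NA")
})

test_that("rerunning on identical bytes reproduces identical assessments", {
  p <- fc_fixture("curated_pmr_like", seed = 11L)
  ctx <- repository_context("PMR-like")
  a1 <- run_assessment(read_archive(p), fc_registry, ctx)
  a2 <- run_assessment(read_archive(p), fc_registry, ctx)
  expect_identical(a1$scores, a2$scores)
})

test_that("validation reports pending and note defects; finalize enforces them", {
  a <- read_archive(fc_fixture("noncurated_pmr_like"))
  ass <- run_assessment(a, fc_registry, repository_context("none"))
  defects <- validate_assessment(ass, fc_registry)
  expect_true(any(defects$defect == "pending"))
  expect_error(finalize_assessment(ass, "error", fc_registry),
               "still pending")
  fin <- finalize_assessment(ass, "zero", fc_registry)
  expect_true(fin$finalized)
  expect_equal(nrow(validate_assessment(fin, fc_registry)), 0L)
  expect_false(any(fin$scores$value == "PENDING"))
  # a hand-built manual 0.5 without note is reported
  broken <- ass
  broken$scores <- fc_set(broken$scores, "CA-RDA-I3-01MM", "0.5",
                          "manual", "")
  d2 <- validate_assessment(broken, fc_registry)
  expect_true(any(d2$defect == "half_score_without_note" &
                    d2$indicator_id == "CA-RDA-I3-01MM"))
})
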