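biom_ctx <- repository_context("BioModels-like")
none_ctx <- repository_context("none")

test_that("standard-format check scores community-standard models as fulfilled", {
  for (preset in c("noncurated_biomodels_like", "noncurated_pmr_like")) {
    a <- read_archive(fc_fixture(preset))
    r <- check_standard_format(a, "Model")
    expect_equal(r$indicator_id, "CA-RDA-R1.3-01Model")
    expect_equal(r$proposed_score, "1")
    ra <- check_standard_format(a, "Archive")
    expect_equal(ra$indicator_id, "CA-RDA-R1.3-01Archive")
    expect_equal(ra$proposed_score, "1")
  }
  # a sole non-standard entry scores 0
  path <- tempfile(fileext = ".zip")
  faircombine:::.write_zip(path, list("stuff.txt" = "not a model"))
  a0 <- read_archive(path)
  expect_equal(check_standard_format(a0, "Model")$proposed_score, "0")
  expect_equal(check_standard_format(a0, "Archive")$proposed_score, "0")
})

test_that("separate-metadata check distinguishes file, inline and context", {
  a1 <- read_archive(fc_fixture("curated_biomodels_like"))
  expect_equal(check_separate_metadata(a1, "ModelMetadata")$proposed_score,
               "1")
  # inline-only metadata earns the partial score
  a2 <- read_archive(fc_fixture("noncurated_pmr_like"))
  r2 <- check_separate_metadata(a2, "ModelMetadata", none_ctx)
  expect_equal(r2$proposed_score, "0.5")
  # nothing anywhere scores 0
  path <- tempfile(fileext = ".zip")
  faircombine:::.write_zip(path, list(
    "model.xml" = make_model_file("SBML", FALSE, 1L)))
  a3 <- read_archive(path)
  expect_equal(
    check_separate_metadata(a3, "ModelMetadata", none_ctx)$proposed_score,
    "0")
  expect_equal(
    check_separate_metadata(a3, "ArchiveMetadata", none_ctx)$proposed_score,
    "0")
})

test_that("provenance check follows the partial-score convention", {
  md_full <- read_archive(fc_fixture("curated_biomodels_like"))$metadata
  r <- check_provenance(md_full, none_ctx, "ModelMetadata")
  expect_equal(r$indicator_id, "CA-RDA-R1.2-01MM")
  expect_equal(r$proposed_score, "1")
  # provenance only via the repository: 0.5
  md_none <- read_archive(fc_fixture("curated_pmr_like"))$metadata
  r2 <- check_provenance(md_none, repository_context("PMR-like"),
                         "ModelMetadata")
  expect_equal(r2$proposed_score, "0.5")
  expect_match(r2$rationale, "not available in\\s+separate files")
  # no provenance anywhere: 0
  r3 <- check_provenance(md_none, none_ctx, "ModelMetadata")
  expect_equal(r3$proposed_score, "0")
})

test_that("identifier check grades DOI, local-only and absent identifiers", {
  a_doi <- read_archive(fc_fixture("highly_curated_biomodels_like"))
  r <- check_identifiers(a_doi, a_doi$metadata, none_ctx)
  expect_setequal(r$indicator_id,
                  c("CA-RDA-F1-01Model", "CA-RDA-F1-01Archive",
                    "CA-RDA-F1-02Model", "CA-RDA-F1-02Archive"))
  expect_true(all(r$proposed_score == "1"))
  a_loc <- read_archive(fc_fixture("noncurated_biomodels_like"))
  r2 <- check_identifiers(a_loc, a_loc$metadata, none_ctx)
  expect_true(all(r2$proposed_score == "0.5"))
  a_no <- read_archive(fc_fixture("noncurated_pmr_like"))
  r3 <- check_identifiers(a_no, a_no$metadata, none_ctx)
  expect_true(all(r3$proposed_score == "0"))
})

test_that("access-protocol check scores from the repository context", {
  r <- check_access_protocol(biom_ctx)
  expect_setequal(r$indicator_id,
                  c("CA-RDA-A1-05Model", "CA-RDA-A1.1-01Model"))
  expect_true(all(r$proposed_score == "1"))
  r0 <- check_access_protocol(repository_context("custom",
                                                 has_api_access = FALSE,
                                                 has_free_protocol = TRUE))
  expect_equal(r0$proposed_score[r0$indicator_id == "CA-RDA-A1-05Model"],
               "0")
  expect_equal(r0$proposed_score[r0$indicator_id == "CA-RDA-A1.1-01Model"],
               "1")
  rp <- check_access_protocol(none_ctx)
  expect_true(all(rp$proposed_score == "PENDING"))
})

test_that("licence check honours in-file and repository-wide licences", {
  md_lic <- read_archive(fc_fixture("highly_curated_biomodels_like"))$metadata
  r <- check_license(md_lic, none_ctx)
  expect_equal(r$proposed_score, "1")
  expect_equal(r$provenance, "automatic")
  md_no <- read_archive(fc_fixture("noncurated_biomodels_like"))$metadata
  r2 <- check_license(md_no, biom_ctx)
  expect_equal(r2$proposed_score, "1")
  expect_equal(r2$provenance, "repository-default")
  r3 <- check_license(md_no, none_ctx)
  expect_equal(r3$proposed_score, "0")
})

test_that("reference check emits the I3 pair with entailment", {
  md_q <- read_archive(fc_fixture("curated_biomodels_like"))$metadata
  r <- check_references(md_q, "Archive")
  expect_equal(r$proposed_score[r$indicator_id == "CA-RDA-I3-01Archive"],
               "1")
  expect_equal(r$proposed_score[r$indicator_id == "CA-RDA-I3-02Archive"],
               "1")
  md_u <- read_archive(fc_fixture("noncurated_biomodels_like"))$metadata
  r2 <- check_references(md_u, "Archive")
  expect_equal(r2$proposed_score, c("1", "0"))
  md_0 <- read_archive(fc_fixture("noncurated_pmr_like"))$metadata
  r3 <- check_references(md_0, "Archive")
  expect_equal(r3$proposed_score, c("0", "0"))
})

test_that("cross-community metadata check recognizes vocabularies", {
  md <- read_archive(fc_fixture("curated_biomodels_like"))$metadata
  expect_equal(
    check_cross_community_metadata(md, "ModelMetadata")$proposed_score, "1")
  # RDF with only custom-namespace terms earns the partial score
  path <- tempfile(fileext = ".zip")
  custom_rdf <- paste0(
    '<?xml version="1.0"?>\n',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '         xmlns:my="http://example.org/myvocab#">\n',
    '  <rdf:Description rdf:about=".">\n',
    '    <my:thing>custom</my:thing>\n',
    '  </rdf:Description>\n',
    '</rdf:RDF>\n')
  faircombine:::.write_zip(path, list(
    "model.xml" = make_model_file("SBML", FALSE, 1L),
    "metadata.rdf" = custom_rdf))
  a <- read_archive(path)
  expect_equal(
    check_cross_community_metadata(a$metadata,
                                   "ModelMetadata")$proposed_score, "0.5")
  # no metadata at all: 0
  md0 <- read_archive(fc_fixture("noncurated_pmr_like"))$metadata
  expect_equal(
    check_cross_community_metadata(md0, "ModelMetadata")$proposed_score, "0")
})

test_that("every check result resolves in the registry with a legal score", {
  for (preset in names(list_presets())) {
    a <- read_archive(fc_fixture(preset))
    res <- run_all_checks(a, biom_ctx)
    expect_true(all(res$indicator_id %in% fc_registry$id))
    expect_true(all(res$proposed_score %in%
                      c("0", "0.5", "1", "NA", "PENDING")))
    expect_true(all(nzchar(res$rationale)))
    # determinism: same bytes, same proposals
    res2 <- run_all_checks(read_archive(fc_fixture(preset)), biom_ctx)
    expect_identical(res, res2)
  }
})

test_that("enriching an archive never lowers any proposed score", {
  rank <- c("0" = 0, "PENDING" = 0, "NA" = 0, "0.5" = 0.5, "1" = 1)
  ladder <- list(
    c("noncurated_biomodels_like", "curated_biomodels_like",
      "highly_curated_biomodels_like"))
  for (fam in ladder) {
    prev <- NULL
    for (preset in fam) {
      a <- read_archive(fc_fixture(preset))
      res <- run_all_checks(a, biom_ctx)
      cur <- setNames(rank[res$proposed_score], res$indicator_id)
      if (!is.null(prev)) {
        shared <- intersect(names(prev), names(cur))
        expect_true(all(cur[shared] >= prev[shared]),
                    info = paste("regression between presets at", preset))
      }
      prev <- cur
    }
  }
})
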