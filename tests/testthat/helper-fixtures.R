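# shared fixtures: registry loaded once; archives built on demand in tempdir
fc_registry <- load_registry()

fc_fixture <- function(preset, seed = 1L, corrupt_metadata = FALSE) {
  path <- tempfile(fileext = ".omex")
  make_archive(preset, path, seed = seed, corrupt_metadata = corrupt_metadata)
  path
}

fc_blank_scores <- function() {
  data.frame(indicator_id = fc_registry$id, value = "PENDING",
             provenance = "pending", note = "", stringsAsFactors = FALSE)
}

fc_set <- function(scores, id, value, provenance = "manual", note = "x") {
  i <- match(id, scores$indicator_id)
  scores$value[i] <- value
  scores$provenance[i] <- provenance
  scores$note[i] <- note
  scores
}

fc_get <- function(scores, id) scores$value[match(id, scores$indicator_id)]
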