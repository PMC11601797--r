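# shared fixtures: a minimal three-screen hierarchy and record builders

fig2_hierarchy <- function() {
  screen_hierarchy(list(
    "626" = list(stage = "primary", parents = character(0)),
    "1488" = list(stage = "confirmatory", parents = "626"),
    "1741" = list(stage = "counter", parents = "1488")
  ))
}

# records with explicit outcomes over the fig2 hierarchy
make_records <- function(smiles, primary = "inactive",
                         confirmatory = "untested", counter = "untested",
                         ids = NULL, inchi = NA) {
  n <- length(smiles)
  if (is.null(ids)) ids <- sprintf("CID%03d", seq_len(n))
  compound_records(
    ids, smiles, inchi,
    outcomes = list("626" = rep_len(primary, n),
                    "1488" = rep_len(confirmatory, n),
                    "1741" = rep_len(counter, n)),
    hierarchy = fig2_hierarchy()
  )
}

# small noiseless campaign reused across curation tests (memoized)
.test_env <- new.env()
noiseless_campaign <- function(n = 300, seed = 7) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.test_env[[key]])) {
    spec <- campaign_spec(
      n_compounds = n, primary_fp_rate = 0, primary_fn_rate = 0,
      counter_cross_react_rate = 0,
      artifact_counts = c(duplicates = 4, mixtures = 4, salts = 4,
                          charged = 4, pains_like = 4, ro5_violators = 4),
      seed = seed)
    .test_env[[key]] <- simulate_screens(generate_library(spec))
  }
  .test_env[[key]]
}

# curated result of the noiseless campaign (pipeline runs are the slow
# part of the suite, so share them across test blocks)
curated_noiseless <- function(n = 300, seed = 7) {
  key <- paste0("cd", n, "_", seed)
  if (is.null(.test_env[[key]])) {
    camp <- noiseless_campaign(n, seed)
    .test_env[[key]] <- run_curation_pipeline(camp$records, camp$hierarchy)
  }
  .test_env[[key]]
}

expect_setequal_chr <- function(a, b) {
  expect_true(setequal(a, b),
              info = paste("sets differ; only in first:",
                           paste(setdiff(a, b), collapse = ","),
                           "only in second:",
                           paste(setdiff(b, a), collapse = ",")))
}
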