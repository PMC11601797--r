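# deduplication, hierarchical labelling and the full pipeline

test_that("duplicates collapse on any shared key, keeping the smallest id", {
  ala <- "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)"
  rec <- make_records(c("CC(N)C(=O)O", "CC(N)C(=O)O", "CCO"),
                      primary = "active", confirmatory = "active",
                      counter = "inactive",
                      ids = c("CID900", "CID100", "CID500"),
                      inchi = c(ala, ala, NA))
  dd <- deduplicate(rec)
  expect_equal(nrow(dd$records), 2)
  expect_true("CID100" %in% dd$records$compound_id)   # lexicographic min kept
  expect_equal(dd$exclusions$compound_id, "CID900")
  expect_equal(dd$exclusions$reason, "duplicate")
})

test_that("conflicting-outcome duplicates are excluded entirely", {
  rec <- make_records(c("CCO", "CCO"), primary = c("active", "inactive"),
                      ids = c("A", "B"))
  dd <- deduplicate(rec)
  expect_equal(nrow(dd$records), 0)
  expect_setequal_chr(dd$exclusions$compound_id, c("A", "B"))
  expect_true(all(dd$exclusions$reason == "conflicting-duplicate"))
})

test_that("all-unique input passes deduplication unchanged", {
  rec <- make_records(c("CCO", "CCC", "CCN"))
  dd <- deduplicate(rec)
  expect_equal(dd$records$compound_id, rec$compound_id)
  expect_equal(nrow(dd$exclusions), 0)
})

test_that("hierarchical labels follow primary -> confirmatory -> counter", {
  h <- fig2_hierarchy()
  rec <- make_records(rep("CCO.CCC", 0))  # placeholder, rebuilt below
  cases <- list(
    list(p = "active", c = "active", k = "inactive", want = "active"),
    list(p = "inactive", c = "untested", k = "untested", want = "inactive"),
    list(p = "active", c = "active", k = "active", want = NA),   # counter hit
    list(p = "active", c = "inactive", k = "untested", want = NA), # unconfirmed
    list(p = "active", c = "untested", k = "untested", want = NA)
  )
  smis <- c("CCO", "CCC", "CCN", "CCCC", "CCCO")
  rec <- compound_records(sprintf("C%d", 1:5), smis,
    outcomes = list(
      "626" = vapply(cases, `[[`, "", "p"),
      "1488" = vapply(cases, `[[`, "", "c"),
      "1741" = vapply(cases, `[[`, "", "k")),
    hierarchy = h)
  res <- assign_hierarchical_labels(rec, h, curation_config())
  expect_equal(res$records$label,
               c("active", "inactive"))
  expect_setequal_chr(res$exclusions$compound_id, c("C3", "C4", "C5"))
  expect_equal(sort(unique(res$exclusions$reason)),
               c("counter-active", "unconfirmed-primary-active"))
  # under the inactive policy, unconfirmed actives stay as inactives
  res2 <- assign_hierarchical_labels(
    rec, h, curation_config(unconfirmed_policy = "inactive"))
  expect_equal(sum(res2$records$label == "inactive"), 3)
})

test_that("outcomes for undeclared screens are a hard error", {
  h <- fig2_hierarchy()
  expect_error(
    compound_records("X", "CCO", outcomes = list("999" = "active"),
                     hierarchy = h),
    "undeclared")
})

test_that("pipeline conserves counts and attributes exclusions to the first failing stage", {
  camp <- noiseless_campaign()
  cd <- curated_noiseless()
  sc <- cd$report$stage_counts
  expect_true(all(sc$n_in == sc$n_out + sc$n_excluded))
  # chained: each stage consumes the previous stage's output
  expect_equal(sc$n_in[-1], sc$n_out[-nrow(sc)])
  expect_equal(sc$n_in[1], nrow(camp$records))
  expect_equal(sc$n_out[nrow(sc)], nrow(cd$records))
  # every excluded id appears exactly once
  expect_equal(anyDuplicated(cd$report$exclusions$compound_id), 0)
  expect_equal(nrow(camp$records),
               nrow(cd$records) + nrow(cd$report$exclusions))
})

test_that("per-stage exclusions equal the simulator's expected counts", {
  camp <- noiseless_campaign()
  cd <- curated_noiseless()
  got <- stats::setNames(cd$report$stage_counts$n_excluded,
                         cd$report$stage_counts$stage)
  expect_equal(got, expected_curation_counts(camp))
})

test_that("pipeline is idempotent on its own output", {
  camp <- noiseless_campaign()
  cd <- curated_noiseless()
  cd2 <- run_curation_pipeline(cd$records, camp$hierarchy)
  expect_equal(nrow(cd2$report$exclusions), 0)
  expect_equal(cd2$records$compound_id, cd$records$compound_id)
  expect_equal(cd2$records$smiles, cd$records$smiles)
  expect_equal(cd2$records$label, cd$records$label)
})

test_that("records failing the parser never reach later stage counts", {
  h <- fig2_hierarchy()
  # a quinone (PAINS) with a broken ring bond: must die at parse, not pains
  rec <- make_records(c("O=C1C=CC(=O)C=C", "O=C1C=CC(=O)C=C1", "CCO"),
                      primary = "inactive")
  cd <- run_curation_pipeline(rec, h)
  ex <- cd$report$exclusions
  expect_equal(ex$stage[ex$compound_id == "CID001"], "parse")
  expect_equal(ex$stage[ex$compound_id == "CID002"], "pains")
  sc <- cd$report$stage_counts
  expect_equal(sc$n_excluded[sc$stage == "pains"], 1)
})

test_that("empty input yields an empty dataset and an all-zero report", {
  h <- fig2_hierarchy()
  rec <- make_records(character(0))
  cd <- run_curation_pipeline(rec, h)
  expect_equal(nrow(cd$records), 0)
  expect_true(all(cd$report$stage_counts$n_excluded == 0))
})

test_that("strict mode turns audit flags into flag-review exclusions", {
  h <- fig2_hierarchy()
  # representation mismatch: propanol SMILES with ethanol InChI
  rec <- make_records(c("CCCO", "CCO"), primary = "inactive",
                      inchi = c("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", NA))
  lax <- run_curation_pipeline(rec, h, curation_config())
  expect_equal(nrow(lax$records), 2)
  expect_true(any(grepl("representation-mismatch", lax$records$flags)))
  strict <- run_curation_pipeline(rec, h, curation_config(strict = TRUE))
  ex <- strict$report$exclusions
  expect_equal(ex$stage[grepl("CID001", ex$compound_id)], "flag_review")
})
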