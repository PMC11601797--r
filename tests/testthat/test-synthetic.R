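# the campaign simulator: determinism, planted artifacts, screen noise

test_that("libraries are deterministic under seed and differ across seeds", {
  spec <- campaign_spec(n_compounds = 120, seed = 21,
                        artifact_counts = c(duplicates = 2, mixtures = 2,
                                            salts = 2, charged = 2,
                                            pains_like = 2,
                                            ro5_violators = 2))
  c1 <- simulate_screens(generate_library(spec))
  c2 <- simulate_screens(generate_library(spec))
  expect_identical(as.data.frame(c1$records), as.data.frame(c2$records))
  expect_identical(c1$truth, c2$truth)
  spec3 <- campaign_spec(n_compounds = 120, seed = 22,
                         artifact_counts = spec$artifact_counts)
  c3 <- generate_library(spec3)
  expect_false(identical(c1$records$smiles, c3$records$smiles))
})

test_that("zero-artifact libraries pass every structural filter", {
  spec <- campaign_spec(n_compounds = 60, seed = 5,
                        artifact_counts = c(duplicates = 0, mixtures = 0,
                                            salts = 0, charged = 0,
                                            pains_like = 0,
                                            ro5_violators = 0))
  camp <- generate_library(spec)
  smi <- camp$records$smiles
  expect_true(all(filter_parse(smi)$pass))
  expect_true(all(filter_inorganic(smi)$pass))
  expect_true(all(filter_pains(smi)$pass))
  expect_true(all(filter_druglikeness(smi)$pass))
  expect_true(all(lengths(smiles_components(smi)) == 1))
})

test_that("planted PAINS compounds are exactly the catalog matches", {
  spec <- campaign_spec(n_compounds = 100, seed = 13,
                        artifact_counts = c(duplicates = 0, mixtures = 0,
                                            salts = 0, charged = 0,
                                            pains_like = 7,
                                            ro5_violators = 0))
  camp <- generate_library(spec)
  hits <- !filter_pains(camp$records$smiles)$pass
  expect_equal(sum(hits), 7)
  expect_setequal_chr(camp$records$compound_id[hits],
                      camp$truth$compound_id[!is.na(camp$truth$artifact) &
                                               camp$truth$artifact == "pains"])
})

test_that("artifact requests exceeding the library size are rejected", {
  expect_error(campaign_spec(n_compounds = 10,
                             artifact_counts = c(duplicates = 20)),
               "exceed")
})

test_that("noiseless screens reproduce truth through curation", {
  camp <- noiseless_campaign(n = 200, seed = 31)
  cd <- curated_noiseless(n = 200, seed = 31)
  finals <- cd$records$compound_id[cd$records$label == "active"]
  trues <- camp$truth$compound_id[camp$truth$true_active &
                                    is.na(camp$truth$artifact)]
  expect_setequal_chr(finals, trues)
})

test_that("a loose primary threshold inflates the primary-active set ~ (hit + fp)/hit", {
  spec <- campaign_spec(n_compounds = 1500, true_hit_rate = 0.005,
                        primary_fp_rate = 0.3, primary_fn_rate = 0,
                        counter_cross_react_rate = 0,
                        artifact_counts = c(duplicates = 0, mixtures = 0,
                                            salts = 0, charged = 0,
                                            pains_like = 0,
                                            ro5_violators = 0),
                        seed = 99)
  camp <- simulate_screens(generate_library(spec))
  n_true <- sum(camp$truth$true_active)
  n_prim <- sum(camp$records$aid_primary == "active")
  # expected primary actives: n_true + fp * (n - n_true); 3 sigma binomial
  n <- nrow(camp$records)
  expe <- n_true + 0.3 * (n - n_true)
  sd3 <- 3 * sqrt(n * 0.3 * 0.7)
  expect_lt(abs(n_prim - expe), sd3)
  # curation recovers truth despite the noise: confirmatory refutations drop
  cd <- run_curation_pipeline(camp$records, camp$hierarchy)
  finals <- cd$records$compound_id[cd$records$label == "active"]
  expect_setequal_chr(finals, camp$truth$compound_id[camp$truth$true_active])
})

test_that("compounds untested in the confirmatory tier are never active", {
  camp <- noiseless_campaign(n = 200, seed = 31)
  cd <- curated_noiseless(n = 200, seed = 31)
  df <- as.data.frame(cd$records)
  act <- df[df$label == "active", ]
  expect_true(all(act$aid_confirmatory == "active"))
  expect_true(all(act$aid_counter != "active"))
})

test_that("expected counts and the pipeline agree on a noisy campaign", {
  spec <- campaign_spec(n_compounds = 250, true_hit_rate = 0.02,
                        primary_fp_rate = 0.25, primary_fn_rate = 0.05,
                        counter_cross_react_rate = 0.1,
                        artifact_counts = c(duplicates = 3, mixtures = 3,
                                            salts = 3, charged = 3,
                                            pains_like = 3,
                                            ro5_violators = 3),
                        seed = 55)
  camp <- simulate_screens(generate_library(spec))
  cd <- run_curation_pipeline(camp$records, camp$hierarchy)
  got <- stats::setNames(cd$report$stage_counts$n_excluded,
                         cd$report$stage_counts$stage)
  expect_equal(got, expected_curation_counts(camp))
})
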