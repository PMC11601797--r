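# compound table reading, flagging rules, SDF round trips, statistics

test_that("compound tables read with outcome decoding and audit flags", {
  h <- fig2_hierarchy()
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(
    "compound_id,smiles,inchi,626,1488,1741",
    # alanine: non-isomeric SMILES but InChI with a /t stereo layer
    "CID001,CC(N)C(=O)O,\"InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)/t2-/m0/s1\",A,A,I",
    # non-standard InChI prefix: flagged but retained
    "CID002,CCO,\"InChI=1/C2H6O/c1-2-3/h3H,2H2,1H3\",I,U,U",
    "CID003,C[C@H](N)C(=O)O,\"InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)/t2-/m0/s1\",A,A,A"
  ), tmp)
  rec <- read_compound_table(tmp, h)
  expect_equal(nrow(rec), 3)  # no row silently dropped
  fl <- record_flags(rec)
  expect_true("non-isomeric-smiles" %in% fl[[1]])
  expect_true("nonstandard-inchi" %in% fl[[2]])
  expect_equal(length(fl[[3]]), 0)
  expect_equal(rec[["626"]], c("active", "inactive", "active"))
  expect_equal(rec[["1488"]][2], "untested")
})

test_that("missing required columns and unknown codes are handled", {
  h <- fig2_hierarchy()
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "x,CCO"), tmp)
  expect_error(read_compound_table(tmp, h), "compound_id")
  writeLines(c("compound_id,626", "x,A"), tmp)
  expect_error(read_compound_table(tmp, h), "smiles")
  writeLines(c("compound_id,smiles,626", "x,CCO,WEIRD"), tmp)
  expect_warning(rec <- read_compound_table(tmp, h), "inconclusive")
  expect_equal(rec[["626"]], "inconclusive")
  writeLines("compound_id,smiles,626", tmp)
  expect_warning(rec0 <- read_compound_table(tmp, h), "no data rows")
  expect_equal(nrow(rec0), 0)
})

test_that("SDF conformers round-trip coordinates at 4 decimals", {
  set.seed(11)
  conf <- list(
    W1 = list(coords = matrix(0, 1, 3), elements = "O",
              flags = character(0)),
    M2 = list(coords = round(matrix(rnorm(15, sd = 3), 5, 3), 4),
              elements = c("C", "C", "N", "O", "S"), flags = character(0))
  )
  tmp <- tempfile(fileext = ".sdf")
  write_sdf_conformers(conf, tmp)
  back <- suppressWarnings(read_sdf_conformers(tmp))
  expect_setequal_chr(names(back), c("W1", "M2"))
  expect_equal(unname(back$M2$coords), unname(conf$M2$coords),
               tolerance = 1e-9)
  expect_equal(back$M2$elements, conf$M2$elements)
  expect_true("no-3d" %in% back$W1$flags)  # all-zero coordinates flagged
})

test_that("duplicate SDF ids: last occurrence wins with a warning", {
  conf <- list(A = list(coords = matrix(1, 1, 3), elements = "C",
                        flags = character(0)))
  tmp <- tempfile(fileext = ".sdf")
  write_sdf_conformers(conf, tmp)
  conf$A$coords <- matrix(2, 1, 3)
  # append a second block with the same id
  t2 <- tempfile(); write_sdf_conformers(conf, t2)
  writeLines(c(readLines(tmp), readLines(t2)), tmp)
  expect_warning(back <- read_sdf_conformers(tmp), "last occurrence")
  expect_equal(unname(back$A$coords[1, 1]), 2)
})

test_that("curated dataset export is deterministic and sorted", {
  rec <- make_records(c("CCO", "CCC", "CCN"), ids = c("B2", "A1", "C3"))
  rec$label <- c("active", "inactive", "inactive")
  d1 <- file.path(tempdir(), "out1"); d2 <- file.path(tempdir(), "out2")
  m1 <- write_curated_dataset(rec, d1, c("smiles_csv", "inchi_csv"))
  m2 <- write_curated_dataset(rec[c(3, 1, 2), ], d2,
                              c("smiles_csv", "inchi_csv"))
  expect_equal(m1$n_records, 3)
  f1 <- readLines(file.path(d1, "curated_smiles.csv"))
  f2 <- readLines(file.path(d2, "curated_smiles.csv"))
  expect_identical(f1, f2)            # order-independent, byte-identical
  expect_equal(f1[2], "A1,CCC,inactive")
})

test_that("dataset statistics reproduce printed percent-active arithmetic", {
  expect_equal(percent_active(60706, 164)$display, "0.270%")
  expect_equal(percent_active(1000, 0)$display, "0.000%")
  rec <- make_records(rep("CCO", 10), ids = sprintf("X%02d", 1:10))
  rec$label <- c(rep("active", 2), rep("inactive", 8))
  scafs <- rep(c("s1", "s2", "s3"), length.out = 10)
  st <- dataset_stats(rec, scaffold_fn = function(s) scafs)
  expect_equal(st$n_compounds, 10)
  expect_equal(st$n_actives, 2)
  expect_equal(st$n_unique_scaffolds, 3)
  expect_warning(st0 <- dataset_stats(rec[0, ]), "zero records")
  expect_equal(st0$n_compounds, 0)
  expect_equal(st0$percent_active_display, "0.000%")
})
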