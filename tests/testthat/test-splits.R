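# split schemes: adapted CV and scaffold split

test_that("adapted CV partitions ids with cyclic validation folds", {
  ids <- sprintf("M%03d", 1:103)
  plan <- adapted_cv_folds(ids, split_config(k = 5, seed = 3))
  expect_equal(length(plan$folds), 5)
  tests <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_equal(sort(tests), sort(ids))           # every id tested once
  expect_equal(anyDuplicated(tests), 0)
  for (t in seq_along(plan$folds)) {
    f <- plan$folds[[t]]
    all3 <- c(f$train, f$val, f$test)
    expect_equal(sort(all3), sort(ids))          # union is everything
    expect_equal(anyDuplicated(all3), 0)         # pairwise disjoint
    # validation fold = cyclic predecessor of the test fold
    v_expect <- plan$folds[[((t - 2) %% 5) + 1]]$test
    expect_setequal_chr(f$val, v_expect)
  }
})

test_that("adapted CV is seed-deterministic and errors on tiny input", {
  ids <- letters
  p1 <- adapted_cv_folds(ids, split_config(seed = 9))
  p2 <- adapted_cv_folds(ids, split_config(seed = 9))
  p3 <- adapted_cv_folds(ids, split_config(seed = 10))
  expect_identical(p1$folds, p2$folds)
  expect_false(identical(p1$folds, p3$folds))
  expect_error(adapted_cv_folds(letters[1:4], split_config(k = 5)),
               "at least k")
})

test_that("scaffold split forces dominant bins into train and stays disjoint", {
  # synthetic scaffold structure: one bin with 15% of molecules, many small
  set.seed(5)
  n <- 400
  scafs <- c(rep("BIG", 60), sprintf("s%03d", sample(80, n - 60, TRUE)))
  rec <- data.frame(compound_id = sprintf("M%03d", 1:n),
                    smiles = rep("c1ccccc1", n), stringsAsFactors = FALSE)
  plan <- scaffold_split(rec, split_config(seed = 2), scaffolds = scafs)
  f <- plan$folds[[1]]
  expect_equal(sort(c(f$train, f$val, f$test)), sort(rec$compound_id))
  # the 15% bin is entirely in train
  big_ids <- rec$compound_id[scafs == "BIG"]
  expect_true(all(big_ids %in% f$train))
  # scaffold disjointness across partitions
  by_part <- list(train = unique(plan$scaffold_map[f$train]),
                  val = unique(plan$scaffold_map[f$val]),
                  test = unique(plan$scaffold_map[f$test]))
  expect_equal(length(intersect(by_part$train, by_part$val)), 0)
  expect_equal(length(intersect(by_part$train, by_part$test)), 0)
  expect_equal(length(intersect(by_part$val, by_part$test)), 0)
  # proportions near 3:1:1 within one bin's size
  max_bin <- max(table(scafs))
  expect_lt(abs(length(f$train) - 0.6 * n), max_bin + 1)
  expect_lt(abs(length(f$val) - 0.2 * n), max_bin + 1)
  expect_lt(abs(length(f$test) - 0.2 * n), max_bin + 1)
})

test_that("scaffold split uses real Murcko scaffolds and is deterministic", {
  smis <- c("c1ccccc1C", "c1ccccc1CC", "c1ccccc1O",      # benzene bin
            "C1CCCCC1C", "C1CCCCC1N",                    # cyclohexane bin
            "c1ccncc1C", "c1ccncc1CC",                   # pyridine bin
            "CCO", "CCC")                                # acyclic bin ""
  rec <- data.frame(compound_id = sprintf("X%d", seq_along(smis)),
                    smiles = smis, stringsAsFactors = FALSE)
  p1 <- scaffold_split(rec, split_config(seed = 4, big_bin_fraction = 0.9))
  p2 <- scaffold_split(rec, split_config(seed = 4, big_bin_fraction = 0.9))
  expect_identical(p1$folds, p2$folds)
  # same-scaffold molecules always travel together
  f <- p1$folds[[1]]
  benz <- rec$compound_id[1:3]
  where <- vapply(names(f), function(p) any(benz %in% f[[p]]), TRUE)
  expect_equal(sum(where), 1)
  expect_error(
    scaffold_split(rec[1:3, ], split_config()),
    "insufficient-scaffolds")
})

test_that("split plans serialize to per-fold CSVs", {
  plan <- adapted_cv_folds(sprintf("M%02d", 1:20), split_config(seed = 1))
  dir <- file.path(tempdir(), "splits")
  paths <- write_split_plan(plan, dir)
  expect_equal(length(list.files(dir, pattern = "fold_..\\.csv")), 5)
  df <- utils::read.csv(file.path(dir, "fold_01.csv"))
  expect_setequal_chr(unique(df$partition), c("train", "val", "test"))
  expect_equal(nrow(df), 20)
})
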