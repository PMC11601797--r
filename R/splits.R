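# ---------------------------------------------------------------------------
# Benchmark split schemes: adapted k-fold cross-validation (every compound
# tested exactly once, validation fold cyclically preceding the test
# fold) and Bemis-Murcko scaffold splitting (scaffold-disjoint partitions
# with dominant scaffold bins forced into training).
# ---------------------------------------------------------------------------

#' Split configuration
#'
#' @param k number of folds for adapted CV (default 5).
#' @param ratio train:validation:test proportions for the scaffold split
#'   (default `c(3, 1, 1)`).
#' @param big_bin_fraction scaffold bins holding more than this fraction
#'   of all molecules are forced into training (default 0.10).
#' @param seed integer seed driving fold shuffling / bin ordering.
#' @return object of class `split_config`.
#' @export
split_config <- function(k = 5L, ratio = c(3, 1, 1),
                         big_bin_fraction = 0.10, seed = 1L) {
  stopifnot(k >= 3, length(ratio) == 3, all(ratio > 0),
            big_bin_fraction > 0, big_bin_fraction < 1)
  structure(list(k = as.integer(k), ratio = as.numeric(ratio),
                 big_bin_fraction = big_bin_fraction,
                 seed = as.integer(seed)), class = "split_config")
}

.new_split_plan <- function(scheme, folds, seed, scaffold_map = NULL) {
  structure(list(scheme = scheme, folds = folds, seed = seed,
                 scaffold_map = scaffold_map), class = "split_plan")
}

#' Adapted k-fold cross-validation plan
#'
#' Shuffles the ids into k near-equal folds. Fold t serves as the test
#' set of tuple t; its cyclic predecessor is the validation set and the
#' remaining k-2 folds form the training set. Every id is tested exactly
#' once across the k tuples while only k models need training.
#'
#' @param ids character or integer vector of compound ids.
#' @param config a [split_config()].
#' @return object of class `split_plan` whose `folds` is a list of k
#'   lists with elements `train`, `val`, `test`.
#' @export
adapted_cv_folds <- function(ids, config = split_config()) {
  k <- config$k
  if (length(ids) < k) {
    stop("need at least k = ", k, " ids, got ", length(ids))
  }
  if (anyDuplicated(ids)) stop("ids must be unique")
  rng <- .seeded_rng(config$seed)
  perm <- ids[rng$sample(length(ids))]
  fold_of <- rep(seq_len(k), length.out = length(ids))
  fold_sets <- split(perm, fold_of)
  folds <- lapply(seq_len(k), function(t) {
    v <- ((t - 2) %% k) + 1  # cyclic predecessor
    list(train = unname(unlist(fold_sets[-c(t, v)])),
         val = fold_sets[[v]],
         test = fold_sets[[t]])
  })
  .new_split_plan("adapted_cv", folds, config$seed)
}

# localized RNG so split plans do not disturb the caller's random stream
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  env$with <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    expr
  }
  env$sample <- function(n, size = n) env$with(sample.int(n, size))
  env$runif <- function(n) env$with(stats::runif(n))
  env
}

#' Bemis-Murcko scaffold split
#'
#' Bins compounds by scaffold string (acyclic molecules share the empty
#' scaffold bin). Bins holding more than `big_bin_fraction` of all
#' molecules go to training outright; the remaining bins are shuffled by
#' the seed, ordered by decreasing size, and greedily assigned to the
#' partition furthest below its target proportion. No scaffold ever spans
#' two partitions.
#'
#' @param records a `compound_records` table or data.frame with columns
#'   `compound_id` and `smiles`.
#' @param config a [split_config()].
#' @param scaffolds optional pre-computed scaffold strings (same length
#'   as `records`); computed with [murcko_scaffold()] when missing.
#' @return a `split_plan` with a single fold and the scaffold map.
#' @export
scaffold_split <- function(records, config = split_config(),
                           scaffolds = NULL) {
  ids <- records$compound_id
  if (is.null(scaffolds)) scaffolds <- murcko_scaffold(records$smiles)
  scaffolds[is.na(scaffolds)] <- ""
  bins <- split(ids, scaffolds)
  if (length(bins) < 3) {
    stop("insufficient-scaffolds: need at least 3 distinct scaffold bins, got ",
         length(bins))
  }
  n <- length(ids)
  sizes <- lengths(bins)
  forced <- sizes > config$big_bin_fraction * n
  assign_to <- stats::setNames(rep(NA_character_, length(bins)), names(bins))
  assign_to[forced] <- "train"
  counts <- c(train = sum(sizes[forced]), val = 0, test = 0)
  target <- config$ratio / sum(config$ratio) * n
  rest <- which(!forced)
  if (length(rest)) {
    rng <- .seeded_rng(config$seed)
    rest <- rest[rng$sample(length(rest))]
    rest <- rest[order(-sizes[rest])]  # stable: ties stay seed-shuffled
    for (b in rest) {
      deficit <- (target - counts) / target
      pick <- names(which.max(deficit))
      assign_to[b] <- pick
      counts[pick] <- counts[pick] + sizes[b]
    }
  }
  fold <- list(
    train = unname(unlist(bins[assign_to == "train"])),
    val = unname(unlist(bins[assign_to == "val"])),
    test = unname(unlist(bins[assign_to == "test"]))
  )
  fold <- lapply(fold, function(x) if (is.null(x)) character(0) else x)
  .new_split_plan("scaffold", list(fold), config$seed,
                  scaffold_map = stats::setNames(scaffolds, ids))
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan (", x$scheme, ", seed ", x$seed, "): ",
      length(x$folds), " fold(s)\n", sep = "")
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("  fold %d: train %d / val %d / test %d\n", i,
                length(f$train), length(f$val), length(f$test)))
  }
  invisible(x)
}

#' Write a split plan to per-fold CSV files
#'
#' @param plan a `split_plan`.
#' @param dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_split_plan <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    df <- data.frame(
      compound_id = c(f$train, f$val, f$test),
      partition = rep(c("train", "val", "test"),
                      c(length(f$train), length(f$val), length(f$test))),
      stringsAsFactors = FALSE
    )
    p <- file.path(dir, sprintf("fold_%02d.csv", i))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
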