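# ---------------------------------------------------------------------------
# Early-recognition metrics for ranked screening results. All four metrics
# reward placing active compounds near the top of the ranked list:
#   * logAUC over a restricted FPR window on a log10 axis,
#   * BEDROC (exponentially weighted early recognition),
#   * enrichment factor in the top-k selection set,
#   * discounted cumulative gain over the top k.
# ---------------------------------------------------------------------------

#' Metric configuration
#'
#' @param fpr_lo,fpr_hi false-positive-rate window for the logAUC
#'   integral, defaults `[0.001, 0.1]` (two decades, so the normalizer is
#'   `log10(fpr_hi) - log10(fpr_lo) = 2`).
#' @param alpha BEDROC early-recognition exponent; 20 focuses roughly on
#'   the top 8% of the list (community convention).
#' @param k size of the selection set for the enrichment factor and DCG
#'   (default 100).
#' @return object of class `metric_config`.
#' @export
metric_config <- function(fpr_lo = 0.001, fpr_hi = 0.1, alpha = 20.0,
                          k = 100L) {
  stopifnot(fpr_lo > 0, fpr_lo < fpr_hi, fpr_hi <= 1, alpha > 0, k >= 1)
  structure(list(fpr_lo = fpr_lo, fpr_hi = fpr_hi, alpha = alpha,
                 k = as.integer(k)), class = "metric_config")
}

.check_labels <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  if (any(is.nan(scores)) || any(is.na(scores))) {
    stop("scores contain NaN/NA")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  invisible(TRUE)
}

.check_degenerate <- function(labels) {
  if (sum(labels) == 0 || sum(labels) == length(labels)) {
    stop("degenerate-labels: need at least one active and one inactive")
  }
}

#' Rank items by decreasing score
#'
#' Stable descending sort. With the default `input_order` tie policy,
#' tied scores keep their input order and a warning is issued; the
#' `average_pessimistic` policy ranks actives last within every tie block,
#' giving the worst-case value of rank-based metrics under ties.
#'
#' @param labels binary vector (1 = active).
#' @param scores numeric vector, higher means predicted more active.
#' @param tie_policy `"input_order"` or `"average_pessimistic"`.
#' @return integer permutation: the item indices in rank order (rank 1
#'   first).
#' @export
rank_by_score <- function(labels, scores,
                          tie_policy = c("input_order",
                                         "average_pessimistic")) {
  tie_policy <- match.arg(tie_policy)
  .check_labels(labels, scores)
  if (anyDuplicated(scores)) {
    if (tie_policy == "input_order") {
      warning("tied scores broken by input order")
      return(order(-scores))
    }
    return(order(-scores, labels))
  }
  order(-scores)
}

# ranked binary labels, the single input every metric consumes
.ranked_labels <- function(labels, scores, tie_policy = "input_order") {
  perm <- suppressWarnings(rank_by_score(labels, scores, tie_policy))
  as.integer(labels[perm])
}

#' logAUC over a restricted false-positive-rate range
#'
#' Builds the empirical ROC curve of the ranking and integrates the true
#' positive rate against log10(FPR) between `fpr_lo` and `fpr_hi`,
#' normalized by the width of the log window. The ROC is a right-
#' continuous step function; the integral sums each TPR plateau times its
#' log-width, with the boundary plateaus clipped at the window edges. A
#' perfect ranking gives 1; a classifier on the identity ROC (TPR = FPR)
#' gives (fpr_hi - fpr_lo)/log(10)/(log10(fpr_hi) - log10(fpr_lo)),
#' about 0.0215 for the default window.
#'
#' @param labels binary vector (1 = active).
#' @param scores numeric score vector.
#' @param config a [metric_config()].
#' @param tie_policy see [rank_by_score()].
#' @return logAUC in `[0, 1]`.
#' @export
logauc_range <- function(labels, scores, config = metric_config(),
                         tie_policy = "input_order") {
  .check_labels(labels, scores)
  .check_degenerate(labels)
  rl <- .ranked_labels(labels, scores, tie_policy)
  .logauc_step(rl, config$fpr_lo, config$fpr_hi)
}

# step-ROC integral of TPR d log10(FPR) over [fpr_lo, fpr_hi], normalized
.logauc_step <- function(ranked_labels, fpr_lo, fpr_hi) {
  n_act <- sum(ranked_labels)
  n_inact <- length(ranked_labels) - n_act
  cum_act <- cumsum(ranked_labels)
  inact_pos <- which(ranked_labels == 0)
  # TPR on the FPR plateau [ (j-1)/n_inact, j/n_inact ) equals the
  # fraction of actives ranked before the j-th inactive; after the last
  # inactive TPR is 1 but FPR is already 1, outside any proper window.
  tpr_before <- cum_act[inact_pos] / n_act  # labels there are 0
  j <- seq_len(n_inact)
  f0 <- pmax((j - 1) / n_inact, fpr_lo)
  f1 <- pmin(j / n_inact, fpr_hi)
  w <- ifelse(f1 > f0, log10(f1) - log10(pmax(f0, .Machine$double.xmin)), 0)
  sum(tpr_before * w) / (log10(fpr_hi) - log10(fpr_lo))
}

#' BEDROC: Boltzmann-enhanced discrimination of ROC
#'
#' Exponentially weighted early-recognition score in `[0, 1]`; weights
#' decay as `exp(-alpha * rank / N)`, so `alpha` controls how early the
#' "early" part of the list is.
#'
#' @inheritParams logauc_range
#' @return BEDROC value in `[0, 1]`.
#' @export
bedroc <- function(labels, scores, config = metric_config(),
                   tie_policy = "input_order") {
  .check_labels(labels, scores)
  .check_degenerate(labels)
  rl <- .ranked_labels(labels, scores, tie_policy)
  .bedroc_from_ranked(rl, config$alpha)
}

.bedroc_from_ranked <- function(ranked_labels, alpha) {
  bign <- length(ranked_labels)
  n <- sum(ranked_labels)
  ra <- n / bign
  ranks <- which(ranked_labels == 1)
  # RIE: observed exponential rank sum over its uniform-ranking expectation
  rie <- sum(exp(-alpha * ranks / bign)) * (exp(alpha / bign) - 1) /
    (ra * (1 - exp(-alpha)))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Enrichment factor in the top-k selection set
#'
#' Ratio of the active fraction among the k top-ranked compounds to the
#' active fraction of the whole library; 1 is random, `n/k`-capped values
#' above 1 indicate enrichment.
#'
#' @inheritParams logauc_range
#' @return enrichment factor (non-negative).
#' @export
enrichment_factor <- function(labels, scores, config = metric_config(),
                              tie_policy = "input_order") {
  .check_labels(labels, scores)
  if (sum(labels) == 0) stop("degenerate-labels: no actives")
  if (length(labels) < config$k) {
    stop("list-shorter-than-k: n = ", length(labels), " < k = ", config$k)
  }
  rl <- .ranked_labels(labels, scores, tie_policy)
  (sum(rl[seq_len(config$k)]) / config$k) /
    (sum(rl) / length(rl))
}

#' Discounted cumulative gain over the top k
#'
#' Binary relevance DCG: each active at rank i in the top k contributes
#' `1 / log2(i + 1)`, so rank 1 is undiscounted.
#'
#' @inheritParams logauc_range
#' @return DCG value (non-negative).
#' @export
dcg_at_k <- function(labels, scores, config = metric_config(),
                     tie_policy = "input_order") {
  .check_labels(labels, scores)
  if (length(labels) < config$k) {
    stop("list-shorter-than-k: n = ", length(labels), " < k = ", config$k)
  }
  rl <- .ranked_labels(labels, scores, tie_policy)
  i <- seq_len(config$k)
  sum(rl[i] / log2(i + 1))
}

#' Evaluate all four early-recognition metrics on one ranking
#'
#' @inheritParams logauc_range
#' @return object of class `metric_report`: list with `logauc`, `bedroc`,
#'   `ef_k`, `dcg_k`, plus the configuration used.
#' @export
evaluate_all <- function(labels, scores, config = metric_config(),
                         tie_policy = "input_order") {
  .check_labels(labels, scores)
  .check_degenerate(labels)
  if (length(labels) < config$k) {
    stop("list-shorter-than-k: n = ", length(labels), " < k = ", config$k)
  }
  rl <- .ranked_labels(labels, scores, tie_policy)
  i <- seq_len(config$k)
  structure(list(
    logauc = .logauc_step(rl, config$fpr_lo, config$fpr_hi),
    bedroc = .bedroc_from_ranked(rl, config$alpha),
    ef_k = (sum(rl[i]) / config$k) / (sum(rl) / length(rl)),
    dcg_k = sum(rl[i] / log2(i + 1)),
    config = config
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Early-recognition metrics (alpha = %g, k = %d, FPR window [%g, %g])\n",
    x$config$alpha, x$config$k, x$config$fpr_lo, x$config$fpr_hi))
  cat(sprintf("  logAUC : %.4f\n  BEDROC : %.4f\n  EF_%-3d : %.3f\n  DCG_%-3d: %.3f\n",
              x$logauc, x$bedroc, x$config$k, x$ef_k, x$config$k, x$dcg_k))
  invisible(x)
}
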