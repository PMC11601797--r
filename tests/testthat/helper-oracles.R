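# independent brute-force/closed-form oracles for the metric suite

# numeric integration of the step ROC over the breakpoint union, with
# TPR(f) evaluated by direct counting at (geometric) interval midpoints
oracle_logauc <- function(ranked, lo = 0.001, hi = 0.1) {
  n_act <- sum(ranked)
  n_in <- length(ranked) - n_act
  inact_pos <- which(ranked == 0)
  tpr_at <- function(f) {
    j <- floor(f * n_in + 1e-12)
    upto <- if (j >= n_in) length(ranked) else inact_pos[j + 1] - 1
    sum(ranked[seq_len(upto)]) / n_act
  }
  bp <- sort(unique(c(lo, hi, (0:n_in) / n_in)))
  bp <- bp[bp >= lo & bp <= hi]
  if (bp[1] > lo) bp <- c(lo, bp)
  if (bp[length(bp)] < hi) bp <- c(bp, hi)
  area <- 0
  for (i in seq_len(length(bp) - 1)) {
    mid <- sqrt(bp[i] * bp[i + 1])
    area <- area + tpr_at(mid) * (log10(bp[i + 1]) - log10(bp[i]))
  }
  area / (log10(hi) - log10(lo))
}

# closed-form early-recognition expression evaluated directly from ranks
oracle_bedroc <- function(ranked, alpha = 20) {
  bign <- length(ranked); n <- sum(ranked); ra <- n / bign
  s <- sum(exp(-alpha * which(ranked == 1) / bign))
  rand <- n / bign * (1 - exp(-alpha)) / (exp(alpha / bign) - 1)
  rie <- s / rand
  factor <- ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra))
  rie * factor + 1 / (1 - exp(alpha * (1 - ra)))
}

rand_instance <- function(n) {
  labels <- rbinom(n, 1, runif(1, 0.05, 0.4))
  if (sum(labels) == 0) labels[sample(n, 1)] <- 1
  if (sum(labels) == n) labels[sample(n, 1)] <- 0
  list(labels = labels, scores = runif(n))
}
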