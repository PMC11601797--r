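# early-recognition metrics against independent oracles

test_that("ranking is a stable descending sort with tie policies", {
  expect_equal(rank_by_score(c(0, 0, 0), c(0.9, 0.1, 0.5)), c(1, 3, 2))
  expect_warning(perm <- rank_by_score(c(1, 0, 1), c(1, 1, 1)),
                 "tied")
  expect_equal(perm, 1:3)                          # input order preserved
  pess <- rank_by_score(c(1, 0, 1), c(1, 1, 1), "average_pessimistic")
  expect_equal(pess, c(2, 1, 3))                   # actives last in tie block
  expect_error(rank_by_score(c(1, 0), c(NaN, 1)), "NaN")
  # the top-scored item always gets rank 1 (exhaustive, n <= 5)
  for (n in 2:5) {
    for (r in 1:10) {
      sc <- sample(seq_len(n) / n)
      expect_equal(rank_by_score(rep(0, n), sc)[1], which.max(sc))
    }
  }
})

test_that("logAUC hits its calibration anchors", {
  n <- 20000; na <- 200
  perfect <- c(rep(1, na), rep(0, n - na))
  expect_equal(logauc_range(perfect, seq(n, 1)), 1.0)
  # score-independent classifier: ROC hugs the identity, value ~ 0.0215
  unif <- rep(c(1, rep(0, 99)), length.out = n)
  v <- logauc_range(unif, seq(n, 1))
  expect_equal(v, 0.099 / (2 * log(10)), tolerance = 0.05)
  expect_error(logauc_range(rep(1, 10), runif(10)), "degenerate")
  expect_error(logauc_range(rep(0, 10), runif(10)), "degenerate")
})

test_that("logAUC equals breakpoint-exact grid integration on random instances", {
  set.seed(401)
  for (r in 1:60) {
    inst <- rand_instance(sample(20:500, 1))
    perm <- order(-inst$scores)
    ranked <- inst$labels[perm]
    expect_equal(logauc_range(inst$labels, inst$scores),
                 oracle_logauc(ranked), tolerance = 1e-9)
  }
  # hand-built case: 20 compounds, actives at ranks 1 and 10
  ranked <- rep(0, 20); ranked[c(1, 10)] <- 1
  expect_equal(logauc_range(ranked, seq(20, 1)), oracle_logauc(ranked),
               tolerance = 1e-9)
})

test_that("BEDROC matches the direct formula and its limiting values", {
  set.seed(402)
  for (r in 1:60) {
    inst <- rand_instance(sample(20:500, 1))
    ranked <- inst$labels[order(-inst$scores)]
    expect_equal(bedroc(inst$labels, inst$scores), oracle_bedroc(ranked),
                 tolerance = 1e-12)
  }
  n <- 1000; na <- 10
  best <- c(rep(1, na), rep(0, n - na))
  expect_gt(bedroc(best, seq(n, 1)), 0.99)
  expect_lt(bedroc(rev(best), seq(n, 1)), 0.01)
  # n=10, actives at ranks 1 and 6
  l <- c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(bedroc(l, seq(10, 1)), oracle_bedroc(l), tolerance = 1e-12)
})

test_that("EF and DCG match brute-force counting", {
  set.seed(403)
  for (r in 1:60) {
    inst <- rand_instance(sample(30:500, 1))
    k <- sample(5:20, 1)
    cfg <- metric_config(k = k)
    ranked <- inst$labels[order(-inst$scores)]
    ef_brute <- (sum(ranked[1:k]) / k) / (mean(inst$labels))
    dcg_brute <- 0
    for (i in 1:k) if (ranked[i] == 1) dcg_brute <- dcg_brute + 1 / log2(i + 1)
    expect_equal(enrichment_factor(inst$labels, inst$scores, cfg), ef_brute)
    expect_equal(dcg_at_k(inst$labels, inst$scores, cfg), dcg_brute)
  }
  cfg3 <- metric_config(k = 3)
  expect_equal(dcg_at_k(c(1, 0, 1, 0), c(4, 3, 2, 1), cfg3), 1.5)
  expect_equal(enrichment_factor(c(0, 0, 1, 1), c(4, 3, 2, 1), cfg3),
               (1 / 3) / (1 / 2))
  expect_error(enrichment_factor(c(1, 0), c(2, 1), metric_config(k = 100)),
               "list-shorter-than-k")
  expect_error(enrichment_factor(c(0, 0, 0), c(3, 2, 1),
                                 metric_config(k = 2)), "degenerate|actives")
})

test_that("promoting an active never decreases any metric (n <= 6 here)", {
  cfg <- metric_config(k = 2)
  for (n in 3:6) {
    for (code in seq_len(2^n - 2)) {
      labels <- as.integer(intToBits(code)[1:n])
      scores <- seq(n, 1)  # identity ranking
      base <- evaluate_all(labels, scores, cfg)
      for (pos in which(labels == 1)) {
        if (pos == n || labels[pos + 1] == 1) next
        swapped <- labels
        swapped[c(pos, pos + 1)] <- swapped[c(pos + 1, pos)]
        # the swapped vector ranks the active one place LOWER; so compare
        # base (better) against swapped (worse): all metrics must not rise
        worse <- evaluate_all(swapped, scores, cfg)
        expect_lte(worse$logauc, base$logauc + 1e-12)
        expect_lte(worse$bedroc, base$bedroc + 1e-12)
        expect_lte(worse$ef_k, base$ef_k + 1e-12)
        expect_lte(worse$dcg_k, base$dcg_k + 1e-12)
      }
    }
  }
})

test_that("metrics are invariant to strictly monotone score transforms", {
  set.seed(404)
  inst <- rand_instance(200)
  cfg <- metric_config(k = 20)
  a <- evaluate_all(inst$labels, inst$scores, cfg)
  for (f in list(function(x) 3 * x + 7, function(x) exp(x),
                 function(x) x^3)) {
    b <- evaluate_all(inst$labels, f(inst$scores), cfg)
    expect_equal(unclass(a)[1:4], unclass(b)[1:4], tolerance = 1e-12)
  }
})

test_that("evaluate_all agrees with the individual metric calls", {
  set.seed(405)
  inst <- rand_instance(300)
  cfg <- metric_config(k = 25)
  r <- evaluate_all(inst$labels, inst$scores, cfg)
  expect_equal(r$logauc, logauc_range(inst$labels, inst$scores, cfg))
  expect_equal(r$bedroc, bedroc(inst$labels, inst$scores, cfg))
  expect_equal(r$ef_k, enrichment_factor(inst$labels, inst$scores, cfg))
  expect_equal(r$dcg_k, dcg_at_k(inst$labels, inst$scores, cfg))
  expect_error(evaluate_all(rep(1, 50), runif(50), metric_config(k = 10)),
               "degenerate")
})
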