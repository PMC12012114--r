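test_that("target patterns are generated to count, normalized and distinct", {
  tg <- make_targets(12, 25, seed = 1)
  expect_identical(nrow(tg), 12L)
  expect_true(all(lengths(tg$values) == 25))
  for (v in tg$values) expect_equal(median(v), 0, tolerance = 1e-9)
  expect_identical(make_targets(12, 25, seed = 1)$values, tg$values)
  # pairwise distinct
  D <- pairwise_dtwd(tg$values)
  expect_gt(min(D[upper.tri(D)]), 0)
  expect_error(make_targets(100, 25), "grid")
})

test_that("selected targets beat seed-matched random walks on min distance", {
  tg <- make_targets(12, 25, seed = 1)
  Dt <- pairwise_dtwd(tg$values)
  min_t <- min(Dt[upper.tri(Dt)])
  set.seed(123)
  wins <- 0
  for (trial in 1:100) {
    rw <- lapply(1:12, function(i) {
      x <- cumsum(rnorm(25))
      (x - median(x)) / sd(x)
    })
    Dr <- pairwise_dtwd(rw)
    if (min_t >= min(Dr[upper.tri(Dr)])) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("candidate search returns scored valid sequences per target", {
  km <- fx_kmer_model()
  allowed <- bidirectional_kmers(km)
  tg <- make_targets(3, 25, seed = 2)
  pool <- score_candidates(tg, km, allowed, L = 18, top_n = 10,
                           search_budget = 400, n_starts = 8, seed = 5)
  expect_identical(nrow(pool), 30L)
  expect_true(all(nchar(pool$seq) == 18))
  expect_true(all(pool$score >= 0))
  # every candidate is composed exclusively of allowed k-mers
  for (s in pool$seq) {
    kmers <- substring(s, 1:14, 5:18)
    expect_true(all(kmers %in% allowed))
  }
  # per target, no duplicate sequences and scores sorted ascending
  for (t in unique(pool$source_target)) {
    sc <- pool$score[pool$source_target == t]
    expect_false(is.unsorted(sc))
    expect_identical(anyDuplicated(pool$seq[pool$source_target == t]), 0L)
  }
  # reported scores equal independently recomputed distances
  set.seed(31)
  for (i in sample(nrow(pool), 15)) {
    tgt <- tg$values[[match(pool$source_target[i], tg$pattern_id)]]
    sig <- normalize_segments(predict_levels(pool$seq[i], km), "median_mad")
    expect_equal(pool$score[i], dtwd(sig, tgt), tolerance = 1e-12)
  }
})

test_that("solve_mdp handles the forced and tiny cases exactly", {
  set.seed(7)
  X <- matrix(rnorm(8), 4)
  D <- as.matrix(dist(X))
  # k = M: everything selected, objective is the upper-triangle sum
  all4 <- solve_mdp(D, 4)
  expect_identical(all4$selected, 1:4)
  expect_equal(all4$objective, sum(D[upper.tri(D)]))
  expect_identical(sum(all4$delta), 4L)
  # k = 2: the globally farthest pair
  two <- solve_mdp(D, 2, method = "exhaustive")
  ij <- arrayInd(which.max(D), dim(D))
  expect_identical(two$selected, sort(as.integer(ij)))
  expect_error(solve_mdp(D, 5), "exceeds")
})

test_that("exhaustive >= exchange >= greedy on random instances", {
  set.seed(19)
  for (trial in 1:100) {
    X <- matrix(rnorm(20), 10)
    D <- as.matrix(dist(X))
    ex <- solve_mdp(D, 3, method = "exhaustive")
    sw <- solve_mdp(D, 3, method = "exchange")
    gr <- solve_mdp(D, 3, method = "greedy")
    expect_gte(ex$objective, sw$objective - 1e-12)
    expect_gte(sw$objective, gr$objective - 1e-12)
    # exhaustive solver agrees with an independent brute force
    bf <- mdp_bruteforce(D, 3)
    expect_equal(ex$objective, bf$objective, tolerance = 1e-12)
    expect_identical(ex$selected, bf$selected)
  }
})

test_that("exhaustive matches brute force on all small instances", {
  set.seed(4)
  for (M in c(6, 9, 12)) {
    for (k in 2:4) {
      X <- matrix(rnorm(M * 3), M)
      D <- as.matrix(dist(X))
      ex <- solve_mdp(D, k, method = "exhaustive")
      bf <- mdp_bruteforce(D, k)
      expect_equal(ex$objective, bf$objective, tolerance = 1e-12)
    }
  }
})

test_that("MDP objective is invariant under candidate reordering", {
  set.seed(10)
  X <- matrix(rnorm(40), 20)
  D <- as.matrix(dist(X))
  base <- solve_mdp(D, 5, method = "exchange")$objective
  for (trial in 1:20) {
    perm <- sample(20)
    expect_equal(solve_mdp(D[perm, perm], 5, method = "exchange")$objective,
                 base, tolerance = 1e-9)
  }
})

test_that("greedy beats the average random subset", {
  set.seed(2)
  for (trial in 1:10) {
    X <- matrix(rnorm(30), 15)
    D <- as.matrix(dist(X))
    gr <- solve_mdp(D, 4, method = "greedy")$objective
    rnd <- replicate(200, {
      s <- sample(15, 4)
      sum(D[s, s][upper.tri(D[s, s])])
    })
    expect_gt(gr, mean(rnd))
  }
})

test_that("small design pipeline is deterministic and well-formed", {
  km <- fx_kmer_model()
  des <- design_barcodes(km, k = 4, n_targets = 4, top_n = 8, L = 18,
                         search_budget = 300, n_starts = 6, seed = 11)
  expect_s3_class(des, "barcode_design")
  expect_identical(nrow(des$barcodes), 4L)
  expect_identical(nrow(des$pool), 32L)
  expect_true(all(nchar(des$barcodes$seq) == 18))
  expect_identical(anyDuplicated(des$barcodes$seq), 0L)
  des2 <- design_barcodes(km, k = 4, n_targets = 4, top_n = 8, L = 18,
                          search_budget = 300, n_starts = 6, seed = 11)
  expect_identical(des$barcodes$seq, des2$barcodes$seq)
  expect_equal(des$objective, des2$objective)
  # glance/tidy surface
  g <- glance(des)
  expect_identical(g$pool_size, 32L)
  expect_identical(nrow(tidy(des)), 4L)
})

test_that("design space size matches the closed-form log computation", {
  # independent check via direct lgamma identity
  l <- design_space_log10(18, 12)
  # independent oracle: exact falling-factorial product on the log10 scale
  N <- 4^18
  direct <- sum(log10(N - 0:11)) - log10(factorial(12))
  expect_equal(l, direct, tolerance = 1e-9)
})
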