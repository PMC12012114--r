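test_that("streaming chunks the signal conservatively", {
  reads <- tibble::tibble(read_id = "r1",
                          signal = list(rnorm(3000, 100, 2)),
                          sample_rate = 3012)
  chunks <- stream_reads(reads, chunk_ms = 100, n_channels = 1, seed = 1)
  # 100 ms at 3012 Hz is 301 samples; remainder in the final chunk
  expect_identical(lengths(chunks$samples),
                   c(rep(301L, 9), 3000L - 9L * 301L))
  expect_identical(unlist(chunks$samples), reads$signal[[1]])
  expect_true(chunks$is_read_start[1])
  expect_true(chunks$is_read_end[nrow(chunks)])
})

test_that("round-robin streaming preserves per-read chunk order per channel", {
  km <- fx_kmer_model()
  ds <- fx_dataset_small()[1:8, ]
  chunks <- stream_reads(ds, chunk_ms = 100, n_channels = 2, seed = 3)
  for (ch in 1:2) {
    sub <- chunks[chunks$channel == ch, ]
    # chunk indices within each read are strictly increasing
    for (rid in unique(sub$read_id)) {
      expect_identical(sub$chunk_idx[sub$read_id == rid],
                       seq_len(sum(sub$read_id == rid)))
    }
    # reads appear serially, not interleaved within the channel
    expect_true(!is.unsorted(sub$read_serial))
    # concatenation reconstructs each read
    for (rid in unique(sub$read_id)) {
      expect_identical(unlist(sub$samples[sub$read_id == rid]),
                       ds$signal[[match(rid, ds$read_id)]])
    }
  }
})

test_that("live classification decides shortly after the poly(A) onset", {
  m <- fx_model_small()
  ds <- fx_dataset_small()
  clean <- ds[ds$label != "NOISE", ]
  agree <- 0
  n <- 12
  for (i in seq_len(n)) {
    lc <- live_classify(clean$signal[[i]], m)
    # decision taken within the plateau, not long after its onset
    expect_gte(lc$samples_consumed, clean$adapter_end[i] - 301)
    expect_lte(lc$samples_consumed,
               clean$adapter_end[i] + 301 * 3 + 301)
    off <- predict(m, extract_fingerprints(clean[i, ]))
    if (!is.na(lc$prediction$predicted) &&
        lc$prediction$predicted == off$predicted) {
      agree <- agree + 1
    }
  }
  expect_gte(agree / n, 0.9)
})

test_that("reads without poly(A) stream to no_decision within budget", {
  km <- fx_kmer_model()
  cfg <- sim_config(rna_body_len_nt = 0)
  rd <- simulate_read(fx_barcodes4()[["BC2"]], km, cfg, seed = 4)
  sig <- rd$signal[[1]][seq_len(rd$adapter_end)]
  lc <- live_classify(sig, fx_model_small(), max_samples = 6000)
  expect_identical(lc$prediction$status, "no_decision")
})

test_that("the rejection rule follows the slack threshold", {
  st <- balancer_state(c("b1", "b2", "b3", "b4"), metric = "read_count",
                       slack = 1.2)
  # equal tallies: nobody is over threshold
  for (b in c("b1", "b2", "b3", "b4")) {
    st$reads[b] <- 10
  }
  d <- decide(st, "b1", "classified")
  expect_identical(d$decision, "accept")
  # skewed tallies: barcode 1 leads by more than the slack ratio
  # (100 > 1.2 * max(10, 10, 10) = 12)
  st$reads <- setNames(c(100, 10, 10, 10), names(st$reads))
  d2 <- decide(st, "b1", "classified")
  expect_identical(d2$decision, "reject")
  d3 <- decide(st, "b2", "classified")
  expect_identical(d3$decision, "accept")
  # noise/unclassified are always accepted and never tallied
  d4 <- decide(st, NA_character_, "noise")
  expect_identical(d4$decision, "accept")
  expect_identical(d4$state$reads, st$reads)
  d5 <- decide(st, "b1", "unclassified")
  expect_identical(d5$decision, "accept")
  expect_error(decide(st, "zz", "classified"), "unknown")
})

test_that("tallies update after the decision and stay monotone", {
  st <- balancer_state(c("x", "y"), metric = "adapter_count", slack = 1.5)
  for (i in 1:10) {
    d <- decide(st, "x", "classified", read_bases = 100)
    st <- d$state
  }
  expect_identical(unname(st$adapters["x"]), 10)
  # accepted reads credit read/base tallies; adapter-only reads do not
  st2 <- balancer_state(c("x", "y"))
  d <- decide(st2, "x", "classified", read_bases = 500,
              adapter_only = TRUE)
  expect_identical(unname(d$state$adapters["x"]), 1)
  expect_identical(unname(d$state$reads["x"]), 0)
})

test_that("gini matches the pairwise-difference formula", {
  expect_equal(gini(rep(7, 5)), 0)
  expect_equal(gini(c(0, 0, 0, 100)), 0.75)
  set.seed(2)
  x <- rpois(10, 20) + 1
  expect_equal(gini(3 * x), gini(x), tolerance = 1e-12)
  expect_error(gini(c(0, 0)), "zero")
  expect_error(gini(c(-1, 2)))
})

test_that("balancing reduces skew against a matched control", {
  km <- fx_kmer_model()
  bcs <- fx_barcodes4()[1:2]
  cfg <- sim_config()
  maj <- simulate_dataset(bcs[1], 120, 0, cfg, km, seed = 61)
  mnr <- simulate_dataset(bcs[2], 24, 0, cfg, km, seed = 62)
  mnr$read_id <- paste0("m_", mnr$read_id)
  ds <- dplyr::bind_rows(maj, mnr)
  fps <- extract_fingerprints(ds)
  pr <- predict(fx_model_small(), fps)
  cmp <- balancing_comparison(ds, pr, n_channels = 4, conf_cutoff = 0.5,
                              seed = 5)
  expect_lt(cmp$summary$gini_balanced, cmp$summary$gini_control)
  expect_gte(cmp$summary$min_count_balanced,
             cmp$summary$min_count_control)
  # rejected reads always consume less than their full length
  log <- cmp$balanced$log
  rej <- log[log$decision == "reject", ]
  full_len <- lengths(ds$signal)[match(rej$read_id, ds$read_id)]
  expect_true(all(rej$samples_consumed < full_len))
  # channel-time accounting never exceeds budget plus one read
  expect_true(all(table(log$channel) >= 1))
})

test_that("balancing replays deterministically under a fixed seed", {
  km <- fx_kmer_model()
  ds <- fx_dataset_small()
  fps <- extract_fingerprints(ds)
  pr <- predict(fx_model_small(), fps)
  r1 <- run_balancing_experiment(ds, pr, n_channels = 3, seed = 9)
  r2 <- run_balancing_experiment(ds, pr, n_channels = 3, seed = 9)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$log, r2$log)
  # replaying the decision log reproduces the final tallies
  acc <- r1$log[r1$log$decision == "accept" & !r1$log$adapter_only &
                  r1$log$true_label != "NOISE", ]
  expect_identical(unname(r1$counts[names(r1$counts)]),
                   unname(vapply(names(r1$counts), function(b) {
                     sum(acc$true_label == b)
                   }, numeric(1))))
})
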