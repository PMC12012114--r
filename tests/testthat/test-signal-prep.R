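test_that("LLR changepoint is exact on a noiseless step", {
  sig <- c(rep(90, 3000), rep(110, 2600))
  bd <- detect_boundaries(sig, seg_config())
  expect_true(bd$ok)
  expect_identical(bd$adapter_end, 3000L)
})

test_that("poly(A) onset is recovered within tolerance on simulated reads", {
  ds <- fx_dataset_small()
  clean <- ds[ds$label != "NOISE", ]
  err <- vapply(seq_len(nrow(clean)), function(i) {
    bd <- detect_boundaries(clean$signal[[i]], seg_config())
    expect_true(bd$ok)
    bd$adapter_end - clean$adapter_end[i]
  }, numeric(1))
  expect_gte(mean(abs(err) <= 50), 0.85)
  expect_lte(median(abs(err)), 10)
})

test_that("reads without a poly(A) tail fail with a flag, not an error", {
  km <- fx_kmer_model()
  cfg <- sim_config(rna_body_len_nt = 0)
  rd <- simulate_read(fx_barcodes4()[["BC1"]], km, cfg, seed = 3)
  sig <- rd$signal[[1]][seq_len(rd$adapter_end)]
  bd <- detect_boundaries(sig, seg_config())
  expect_false(bd$ok)
  expect_true("no_polya" %in% bd$qc_flags || "too_short" %in% bd$qc_flags)
})

test_that("segmentation partitions exactly and recovers clean blocks", {
  cfg <- seg_config()
  # constant signal: any partition works, all means equal the constant
  segs <- segment_adapter(rep(3.5, 100), 4, cfg)
  expect_length(segs, 4)
  expect_equal(as.numeric(segs), rep(3.5, 4))
  expect_identical(sum(attr(segs, "lengths")), 100L)

  # 25 distinct constant blocks, changepoints are unique t maxima
  set.seed(6)
  levels <- sample(seq(60, 130, length.out = 25))
  x <- rep(levels, each = 40)
  segs <- segment_adapter(x, 25, cfg)
  expect_equal(as.numeric(segs), levels)
  expect_identical(attr(segs, "lengths"), rep(40L, 25))

  expect_error(segment_adapter(rnorm(10), 25, cfg), "too short")
})

test_that("noisy two-level step boundary is near the brute-force optimum", {
  cfg <- seg_config()
  set.seed(9)
  for (trial in 1:5) {
    x <- c(rnorm(60, 0, 1), rnorm(60, 10, 1))
    segs <- segment_adapter(x, 2, cfg)
    found <- attr(segs, "boundaries")[2]
    # oracle: exhaustive maximizer of the two-segment Welch t-statistic
    tstat <- vapply(2:(length(x) - 2), function(t) {
      a <- x[1:t]
      b <- x[(t + 1):length(x)]
      abs(mean(a) - mean(b)) /
        sqrt(var(a) / length(a) + var(b) / length(b))
    }, numeric(1))
    best <- which.max(tstat) + 1
    expect_lte(abs(found - best), 2)
  }
})

test_that("partition conservation: length-weighted segment means average back", {
  set.seed(14)
  x <- rnorm(541, 100, 10)
  segs <- segment_adapter(x, 25, seg_config())
  w <- attr(segs, "lengths")
  expect_equal(sum(as.numeric(segs) * w) / sum(w), mean(x),
               tolerance = 1e-9)
})

test_that("normalization follows the median/MAD contract", {
  # hand-computed: median 3, raw MAD 1
  x <- c(1, 2, 3, 4, 100)
  nm <- normalize_segments(x, "median_mad")
  expect_equal(nm[3], 0)
  expect_equal(nm[5], 97 / 1.4826, tolerance = 1e-9)

  set.seed(2)
  y <- rnorm(40)
  # affine invariance (positive scale) for both methods
  for (method in c("median_mad", "zscore")) {
    expect_equal(normalize_segments(3.2 * y + 7, method),
                 normalize_segments(y, method), tolerance = 1e-9)
    # idempotence
    ny <- normalize_segments(y, method)
    expect_equal(normalize_segments(ny, method), ny, tolerance = 1e-9)
  }
  # degenerate inputs: MAD 0 falls back to zscore; constant gives zeros
  spike <- c(rep(1, 10), 5)
  expect_equal(normalize_segments(spike, "median_mad"),
               (spike - mean(spike)) / sd(spike))
  expect_identical(normalize_segments(rep(2, 5), "median_mad"), rep(0, 5))
})

test_that("fingerprints have the configured length and propagate QC", {
  cfg <- seg_config()
  expect_identical(cfg$n_segments, 55L)  # round(50 * 1.10)
  fps <- fx_fps_small()
  expect_true(all(lengths(fps$fingerprint[fps$ok]) == 25))
  expect_true(all(vapply(fps$fingerprint[!fps$ok], is.null, logical(1))))
  # failures carry flags rather than raising
  expect_true(all(nzchar(fps$qc_flags[!fps$ok])))
})

test_that("noiseless fingerprint equals the truth-level oracle", {
  km <- fx_kmer_model()
  cfg <- sim_config(noise_sd = 0, dwell_dispersion = 0)
  rd <- simulate_read(fx_barcodes4()[["BC4"]], km, cfg, seed = 8)
  fp <- extract_fingerprint(rd, seg_config())
  expect_true(fp$ok)
  expect_length(fp$values, 25)
  # oracle from simulator truth: without noise or dwell variation, surplus
  # boundaries can only duplicate event levels, so the deduplicated
  # fingerprint must be an exact positive affine image of the trailing true
  # event levels (normalization is affine)
  dedup <- rle(fp$values)$values
  lv <- rd$levels[[1]][1:46]
  ref <- tail(lv, length(dedup))
  fit <- lm(dedup ~ ref)
  expect_gt(coef(fit)[2], 0)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("fingerprint extraction over a read table keeps one row per read", {
  fps <- fx_fps_small()
  ds <- fx_dataset_small()
  expect_identical(nrow(fps), nrow(ds))
  expect_identical(fps$read_id, ds$read_id)
  expect_identical(fps$label, ds$label)
})
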