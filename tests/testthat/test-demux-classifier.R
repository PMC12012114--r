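test_that("training on separable classes yields self-consistent predictions", {
  fps <- fx_gaussian_fps(n_per_class = 30, n_classes = 4, noise = 0.25,
                         seed = 2)
  m <- train_demux(fps, seed = 3)
  expect_s3_class(m, "demux_model")
  expect_identical(sort(m$classes), sort(unique(fps$label)))
  pr <- predict(m, fps, conf_cutoff = 0)
  expect_gte(mean(pr$predicted == fps$label), 0.99)
  g <- glance(m)
  expect_identical(g$n_classes, 4L)
  expect_identical(g$n_train, 120L)
  expect_error(train_demux(fps[1:15, ]), "10 reads|two classes")
})

test_that("training is deterministic under seed", {
  fps <- fx_gaussian_fps(n_per_class = 15, n_classes = 3, seed = 4)
  m1 <- train_demux(fps, seed = 11)
  m2 <- train_demux(fps, seed = 11)
  p1 <- predict(m1, fps)
  p2 <- predict(m2, fps)
  expect_identical(p1, p2)
})

test_that("prediction output satisfies the probability-simplex contract", {
  fps <- fx_gaussian_fps(n_per_class = 20, n_classes = 3, seed = 6)
  m <- train_demux(fps, seed = 1)
  pr <- predict(m, fps, conf_cutoff = 0.3)
  pm <- as.matrix(pr[, grep("^p_", names(pr))])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
  expect_true(all(pm >= 0))
  # confidence is the gap between the two largest probabilities
  gap <- apply(pm, 1, function(r) {
    s <- sort(r, decreasing = TRUE)
    s[1] - s[2]
  })
  expect_equal(pr$confidence, gap, tolerance = 1e-12)
  # predicted label is the argmax
  expect_identical(pr$predicted,
                   sub("^p_", "", colnames(pm)[max.col(pm)]))
})

test_that("status logic follows confidence, noise and QC rules", {
  fps <- fx_gaussian_fps(n_per_class = 15, n_classes = 2, seed = 7)
  noisy <- fps
  noisy$label[noisy$label == "class2"] <- "NOISE"
  m <- train_demux(noisy, seed = 2)
  q <- fx_gaussian_fps(n_per_class = 5, n_classes = 2, seed = 8)
  q$fingerprint[1] <- list(NULL)
  q$ok[1] <- FALSE
  pr <- predict(m, q, conf_cutoff = 0.5)
  expect_identical(pr$status[1], "qc_fail")
  expect_true(is.na(pr$predicted[1]))
  # NOISE top label gets status noise regardless of cutoff
  expect_true(all(pr$status[pr$predicted == "NOISE" & !is.na(pr$predicted)]
                  == "noise"))
  # at cutoff 0 nothing is unclassified
  pr0 <- predict(m, q, conf_cutoff = 0)
  expect_false(any(pr0$status == "unclassified"))
  # at cutoff 1, anything not noise/qc_fail with confidence < 1 drops out
  pr1 <- predict(m, q, conf_cutoff = 1)
  cls <- pr1$status == "classified"
  expect_true(all(pr1$confidence[cls] >= 1 - 1e-12))
  # fingerprint length mismatch is an error
  bad <- tibble::tibble(read_id = "x", fingerprint = list(rnorm(10)),
                        ok = TRUE)
  expect_error(predict(m, bad), "length")
})

test_that("model archives round-trip with bit-identical predictions", {
  fps <- fx_gaussian_fps(n_per_class = 15, n_classes = 3, seed = 9)
  m <- train_demux(fps, seed = 5)
  dir <- withr::local_tempdir()
  save_demux_model(m, file.path(dir, "model"))
  m2 <- load_demux_model(file.path(dir, "model"))
  q <- fx_gaussian_fps(n_per_class = 34, n_classes = 3, seed = 10)
  expect_identical(predict(m, q), predict(m2, q))
  meta <- jsonlite::read_json(file.path(dir, "model", "model.json"))
  expect_identical(meta$fingerprint_len, 25L)
})

test_that("calibration thresholds implement the quantile rule with clamps", {
  # E_b = 0: threshold 0 for every target
  t0 <- calibration_thresholds(rep("a", 100), rep("a", 100), runif(100),
                               target_accuracies = c(95, 99))
  expect_true(all(t0$threshold == 0))
  # E_b = 2%, A_t = 95: q = 1 - 5/2 < 0, clamped to 0
  pred <- rep("a", 100)
  truth <- c(rep("b", 2), rep("a", 98))
  conf <- seq(0.01, 1, length.out = 100)
  t1 <- calibration_thresholds(pred, truth, conf, target_accuracies = 95)
  expect_equal(t1$error_rate[t1$barcode == "a"][1], 2)
  expect_identical(t1$threshold[t1$barcode == "a"], 0)
  # E_b = 10%, A_t = 99: q = 0.9, threshold is the 0.9-quantile of the
  # misclassified confidences (linear interpolation)
  truth10 <- c(rep("b", 10), rep("a", 90))
  conf10 <- c(seq(0.1, 1, length.out = 10), runif(90, 0.9, 1))
  t2 <- calibration_thresholds(rep("a", 100), truth10, conf10,
                               target_accuracies = 99)
  expect_equal(t2$threshold[t2$barcode == "a"],
               quantile(conf10[1:10], 0.9, names = FALSE),
               tolerance = 1e-12)
  # "b" never predicted: flagged with an undefined threshold
  expect_true(all(is.na(t2$threshold[t2$barcode == "b"])))
  # never-predicted barcode flagged with NA
  t3 <- calibration_thresholds(rep("a", 10), c(rep("a", 9), "c"),
                               runif(10), 99)
  expect_true(all(is.na(t3$threshold[t3$barcode == "c"])))
  # thresholds are non-decreasing in the target accuracy
  t4 <- calibration_thresholds(rep("a", 100), truth10, conf10,
                               target_accuracies = c(95, 97, 99, 99.9))
  expect_false(is.unsorted(t4$threshold[t4$barcode == "a"]))
})

test_that("evaluation metrics match their definitions", {
  pred <- tibble::tibble(
    read_id = sprintf("r%d", 1:10),
    predicted = c("a", "a", "b", "b", "a", "b", "a", "b", "NOISE", "a"),
    confidence = c(0.9, 0.8, 0.95, 0.7, 0.2, 0.9, 0.85, 0.6, 0.99, 0.9),
    status = c(rep("classified", 4), "unclassified",
               rep("classified", 3), "noise", "classified"),
    label = c("a", "a", "b", "a", "a", "b", "a", "b", "a", "a"))
  ev <- evaluate_demux(pred)
  # 8 classified (noise and unclassified excluded), 7 correct
  expect_equal(ev$accuracy, 7 / 8)
  expect_equal(ev$unclassified_fraction, 1 / 9)
  expect_equal(ev$noise_fraction, 1 / 10)
  # recall-normalized confusion rows sum to one
  expect_true(all(abs(rowSums(ev$confusion) - 1) < 1e-9))
  tt <- tidy(ev)
  expect_identical(nrow(tt), 2L)
  a <- tt[tt$label == "a", ]
  expect_equal(a$precision, 1)     # all four classified a-predictions hit
  expect_equal(a$recall, 4 / 5)    # one true a was classified as b
  b <- tt[tt$label == "b", ]
  expect_equal(b$precision, 3 / 4)
  expect_equal(b$recall, 1)
  # perfect predictions: accuracy 1, recalls 1, no unclassified
  perfect <- tibble::tibble(read_id = "x", predicted = "a",
                            confidence = 1, status = "classified",
                            label = "a")
  evp <- evaluate_demux(perfect)
  expect_equal(evp$accuracy, 1)
  expect_equal(evp$unclassified_fraction, 0)
})

test_that("accuracy-yield curve trades off monotonically on clean data", {
  for (seed in 1:3) {
    fps <- fx_gaussian_fps(n_per_class = 25, n_classes = 3, noise = 0.9,
                           seed = 20 + seed)
    m <- train_demux(fps[seq(1, nrow(fps), by = 2), ], seed = 1)
    pr <- predict(m, fps[seq(2, nrow(fps), by = 2), ], conf_cutoff = 0)
    ev <- evaluate_demux(pr)
    ok <- !is.na(ev$curve$accuracy)
    # yield shrinks as the cutoff rises; the retained set gets no worse
    expect_true(all(diff(ev$curve$n_classified) <= 0))
    expect_gte(ev$curve$accuracy[max(which(ok))],
               ev$curve$accuracy[1] - 1e-9)
  }
})
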