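# Platt scaling: fit sigmoid P(first class | f) = plogis(b0 + b1 * f) on
# cross-validated decision values, with Platt's regularized targets
# (N+ + 1)/(N+ + 2) and 1/(N- + 2) guarding against overconfidence on
# separable data.
fit_platt <- function(f, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  t <- ifelse(is_pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  fit <- suppressWarnings(
    stats::glm(t ~ f, family = stats::binomial(), control =
                 stats::glm.control(maxit = 50)))
  unname(stats::coef(fit))
}

# pairwise coupling of one-vs-one probabilities into a class simplex,
# second method of Wu, Lin & Weng (2004), as used by libsvm: R[i, j] is the
# calibrated estimate of P(class i | class i or j)
couple_probs <- function(R) {
  k <- nrow(R)
  if (k == 2) return(c(R[1, 2], R[2, 1]))
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(R[-t, t]^2)
    Q[t, -t] <- -R[-t, t] * R[t, -t]
  }
  p <- rep(1 / k, k)
  for (iter in seq_len(100)) {
    Qp <- as.numeric(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < 1e-7) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / sum(p)
}

ksvm_quiet <- function(K, y, C, tol) {
  fit <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(K), y, kernel = "matrix", C = C,
                  tol = tol),
    error = function(e) {
      kernlab::ksvm(kernlab::as.kernelMatrix(K + diag(1e-8, nrow(K))), y,
                    kernel = "matrix", C = C, tol = tol)
    })
  fit
}

decision_values <- function(fit, Krows) {
  as.numeric(kernlab::predict(
    fit, kernlab::as.kernelMatrix(Krows[, kernlab::SVindex(fit),
                                        drop = FALSE]),
    type = "decision"))
}

#' Train the DTW-kernel SVM demultiplexer
#'
#' Builds the full pairwise DTW distance matrix over the training
#' fingerprints, maps it through the exponential kernel
#' `K = exp(-gamma * DTWD)`, and fits a one-vs-one soft-margin SVM
#' (libsvm-based binary machines via kernlab) on the precomputed kernel.
#' Class-membership probabilities are calibrated per class pair by Platt
#' scaling fitted on internal 5-fold cross-validated decision values, and
#' combined into a class simplex by pairwise coupling (the libsvm
#' multiclass-probability scheme). The kernel is not guaranteed positive
#' semidefinite; fits accept the matrix as-is and retry once with a small
#' diagonal jitter on failure.
#'
#' @param train Fingerprint tibble with `fingerprint` (list) and `label`
#'   columns; labels may include `"NOISE"`.
#' @param dtw_cfg A [dtw_config()] (holds the kernel gamma).
#' @param C SVM regularization (default 1).
#' @param seed Integer seed (controls the probability-calibration CV
#'   splits, making training deterministic).
#' @param n_folds Internal CV folds for Platt scaling (default 5).
#' @param svm_tol SMO convergence tolerance (default 0.01; the indefinite
#'   DTW kernel makes the default libsvm tolerance of 0.001 converge very
#'   slowly on heterogeneous class pairs with no measurable gain).
#' @return An object of class `demux_model`.
#' @export
train_demux <- function(train, dtw_cfg = dtw_config(), C = 1, seed = 1,
                        n_folds = 5, svm_tol = 0.01) {
  stopifnot(all(c("fingerprint", "label") %in% names(train)))
  if (length(unique(train$label)) < 2) {
    stop("train_demux: need at least two classes")
  }
  counts <- table(train$label)
  if (any(counts < 10)) {
    stop("train_demux: every class needs >= 10 reads; smallest has ",
         min(counts))
  }
  fp_len <- unique(lengths(train$fingerprint))
  if (length(fp_len) != 1) {
    stop("train_demux: fingerprints have inconsistent lengths")
  }
  fps <- do.call(rbind, train$fingerprint)
  y <- factor(train$label)
  classes <- levels(y)
  D <- pairwise_dtwd(train$fingerprint, cfg = dtw_cfg)
  K <- exp(-dtw_cfg$gamma * D)
  pair_idx <- combn(length(classes), 2)
  pair_models <- withr_seed(seed, {
    # stratified fold assignment, fixed for all pairs
    fold <- integer(length(y))
    for (cl in classes) {
      rows <- which(y == cl)
      fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
    }
    lapply(seq_len(ncol(pair_idx)), function(pi) {
      ci <- classes[pair_idx[1, pi]]
      cj <- classes[pair_idx[2, pi]]
      rows <- which(y %in% c(ci, cj))
      yp <- factor(as.character(y[rows]), levels = c(ci, cj))
      Kp <- K[rows, rows, drop = FALSE]
      fit <- ksvm_quiet(Kp, yp, C, svm_tol)
      cvf <- numeric(length(rows))
      for (fd in seq_len(n_folds)) {
        te <- fold[rows] == fd
        if (!any(te)) next
        mf <- ksvm_quiet(Kp[!te, !te, drop = FALSE], yp[!te], C, svm_tol)
        cvf[te] <- decision_values(mf, Kp[te, !te, drop = FALSE])
      }
      platt <- fit_platt(cvf, yp == ci)
      list(classes = c(ci, cj), rows = rows,
           sv_cols = rows[kernlab::SVindex(fit)],
           svm = fit, platt = platt)
    })
  })
  structure(list(fingerprints = fps,
                 labels = as.character(y),
                 classes = classes,
                 dtw_cfg = dtw_cfg,
                 C = C,
                 seed = seed,
                 n_folds = n_folds,
                 fingerprint_len = fp_len,
                 pair_models = pair_models,
                 format_version = "2.0"),
            class = "demux_model")
}

#' @export
print.demux_model <- function(x, ...) {
  cat("<demux_model>", length(x$classes), "classes,",
      nrow(x$fingerprints), "support fingerprints of length",
      x$fingerprint_len, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  gamma =", x$dtw_cfg$gamma, " C =", x$C, "\n")
  invisible(x)
}

#' @export
glance.demux_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_train = nrow(x$fingerprints),
                 n_support_vectors =
                   length(unique(unlist(lapply(x$pair_models,
                                               `[[`, "sv_cols")))),
                 gamma = x$dtw_cfg$gamma, C = x$C,
                 fingerprint_len = x$fingerprint_len)
}

#' @export
tidy.demux_model <- function(x, ...) {
  dplyr::count(tibble::tibble(label = x$labels), .data$label,
               name = "n_train")
}

#' Classify fingerprints with a trained demultiplexer
#'
#' Computes the DTW kernel between each query fingerprint and the model's
#' support fingerprints, obtains the calibrated class-probability simplex,
#' and derives the confidence score as the gap between the two largest
#' class probabilities. Reads whose top class is `NOISE` get status
#' `"noise"` regardless of the cutoff; reads with confidence strictly below
#' `conf_cutoff` are `"unclassified"`; failed fingerprints are `"qc_fail"`.
#' At `conf_cutoff = 0` no read is unclassified.
#'
#' @param object A `demux_model`.
#' @param fps Fingerprint tibble (rows with `ok = FALSE` or `NULL`
#'   fingerprints are passed through as `qc_fail`), or a numeric matrix of
#'   fingerprints (one per row).
#' @param conf_cutoff Confidence cutoff in `[0, 1]` (default 0).
#' @param ... Unused.
#' @return A tibble with `read_id`, `predicted`, `confidence`, `status` and
#'   one `p_<class>` probability column per class.
#' @export
predict.demux_model <- function(object, fps, conf_cutoff = 0, ...) {
  stopifnot(conf_cutoff >= 0, conf_cutoff <= 1)
  if (is.matrix(fps)) {
    fps <- tibble::tibble(read_id = sprintf("row_%d", seq_len(nrow(fps))),
                          fingerprint = lapply(seq_len(nrow(fps)),
                                               function(i) fps[i, ]),
                          ok = TRUE)
  }
  if (!"ok" %in% names(fps)) fps$ok <- !vapply(fps$fingerprint, is.null,
                                               logical(1))
  ok_rows <- which(fps$ok)
  classes <- object$classes
  probs <- matrix(NA_real_, nrow(fps), length(classes),
                  dimnames = list(NULL, classes))
  if (length(ok_rows) > 0) {
    qlen <- unique(lengths(fps$fingerprint[ok_rows]))
    if (length(qlen) != 1 || qlen != object$fingerprint_len) {
      stop("predict.demux_model: query fingerprint length does not match ",
           "the model's fingerprint_len = ", object$fingerprint_len)
    }
    D <- pairwise_dtwd(fps$fingerprint[ok_rows], object$fingerprints,
                       object$dtw_cfg)
    Kq <- exp(-object$dtw_cfg$gamma * D)
    k <- length(classes)
    # calibrated pairwise one-vs-one probabilities, then coupling
    R_all <- array(0, dim = c(length(ok_rows), k, k))
    for (pm in object$pair_models) {
      f <- decision_values(pm$svm, Kq[, pm$rows, drop = FALSE])
      r <- stats::plogis(pm$platt[1] + pm$platt[2] * f)
      r <- pmin(pmax(r, 1e-7), 1 - 1e-7)
      i <- match(pm$classes[1], classes)
      j <- match(pm$classes[2], classes)
      R_all[, i, j] <- r
      R_all[, j, i] <- 1 - r
    }
    p <- t(apply(R_all, 1, couple_probs))
    probs[ok_rows, ] <- p
  }
  top_idx <- apply(probs, 1, function(r) {
    if (anyNA(r)) NA_integer_ else which.max(r)
  })
  conf <- apply(probs, 1, function(r) {
    if (anyNA(r)) NA_real_ else {
      s <- sort(r, decreasing = TRUE)
      s[1] - s[2]
    }
  })
  predicted <- ifelse(is.na(top_idx), NA_character_, classes[top_idx])
  status <- dplyr::case_when(
    is.na(top_idx) ~ "qc_fail",
    predicted == "NOISE" ~ "noise",
    conf < conf_cutoff ~ "unclassified",
    TRUE ~ "classified"
  )
  out <- tibble::tibble(read_id = fps$read_id, predicted = predicted,
                        confidence = conf, status = status)
  colnames(probs) <- paste0("p_", classes)
  out <- dplyr::bind_cols(out, tibble::as_tibble(probs))
  for (col in c("label", "replicate_id")) {
    if (col %in% names(fps)) out[[col]] <- fps[[col]]
  }
  out
}

#' Per-barcode confidence thresholds for target accuracies
#'
#' Implements accuracy-targeted threshold calibration. For each barcode `b`,
#' the baseline error rate `E_b` (in percent) is the share of misclassified
#' reads among reads *predicted* as `b`. For a target accuracy `A_t` (in
#' percent) the confidence threshold `T` is the linear-interpolation
#' `q`-quantile of the confidence scores of the misclassified reads
#' predicted `b`, with `q = 1 - (100 - A_t) / E_b`. When the baseline
#' already meets the target (`E_b <= 100 - A_t`, so `q <= 0`) the threshold
#' is 0. Confidence scores above `T` are retained.
#'
#' @param predicted,truth Character vectors of predicted and true labels
#'   over classified reads.
#' @param confidence Numeric confidence scores, same length.
#' @param target_accuracies Target accuracy levels in percent.
#' @return A tibble with columns `barcode`, `error_rate` (`E_b`, percent),
#'   `n_predicted`, `target_accuracy`, `threshold`. Barcodes never
#'   predicted get `NA` thresholds.
#' @export
calibration_thresholds <- function(predicted, truth, confidence,
                                   target_accuracies = c(95, 96, 97, 98, 99,
                                                         99.5, 99.9)) {
  stopifnot(length(predicted) == length(truth),
            length(predicted) == length(confidence))
  barcodes <- sort(setdiff(unique(c(predicted, truth)), "NOISE"))
  rows <- lapply(barcodes, function(b) {
    idx <- which(predicted == b)
    if (length(idx) == 0) {
      return(tibble::tibble(barcode = b, error_rate = NA_real_,
                            n_predicted = 0L,
                            target_accuracy = target_accuracies,
                            threshold = NA_real_))
    }
    wrong <- idx[truth[idx] != b]
    e_b <- 100 * length(wrong) / length(idx)
    thr <- vapply(target_accuracies, function(a_t) {
      if (e_b <= (100 - a_t)) return(0)
      q <- 1 - (100 - a_t) / e_b
      if (q <= 0) return(0)
      quantile(confidence[wrong], q, type = 7, names = FALSE)
    }, numeric(1))
    tibble::tibble(barcode = b, error_rate = e_b,
                   n_predicted = length(idx),
                   target_accuracy = target_accuracies, threshold = thr)
  })
  dplyr::bind_rows(rows)
}

#' Calibrate a demultiplexer on held-out reads
#'
#' Predicts the calibration set (disjoint from training), drops noise-status
#' reads, and derives per-barcode confidence thresholds for the requested
#' target accuracies via [calibration_thresholds()]. Barcodes predicted
#' fewer than 50 times are flagged with a warning since their thresholds
#' are unstable.
#'
#' @param model A `demux_model`.
#' @param calib Fingerprint tibble with ground-truth `label`.
#' @param target_accuracies Target accuracies in percent.
#' @return A calibration tibble (see [calibration_thresholds()]).
#' @export
calibrate_demux <- function(model, calib,
                            target_accuracies = c(95, 96, 97, 98, 99, 99.5,
                                                  99.9)) {
  pred <- predict(model, calib, conf_cutoff = 0)
  keep <- pred$status == "classified"
  tab <- calibration_thresholds(pred$predicted[keep], pred$label[keep],
                                pred$confidence[keep], target_accuracies)
  low <- unique(tab$barcode[!is.na(tab$n_predicted) & tab$n_predicted < 50])
  if (length(low) > 0) {
    warning("calibrate_demux: fewer than 50 predictions for barcode(s) ",
            paste(low, collapse = ", "), "; thresholds unstable")
  }
  tab
}

#' Evaluate predictions against ground truth
#'
#' Computes accuracy over classified reads (noise-status reads are excluded
#' from performance assessment, unclassified reads are excluded but
#' counted), per-class precision and recall with macro averages, the
#' recall-normalized confusion matrix (rows = true label, rows sum to 1),
#' and an accuracy-vs-yield curve over a grid of confidence cutoffs.
#'
#' @param pred Prediction tibble from [predict.demux_model()].
#' @param truth Character vector of true labels; defaults to `pred$label`.
#' @param cutoff_grid Confidence cutoffs for the trade-off curve.
#' @return An object of class `demux_eval`.
#' @export
evaluate_demux <- function(pred, truth = pred$label,
                           cutoff_grid = seq(0, 0.95, by = 0.05)) {
  stopifnot(length(truth) == nrow(pred))
  eligible <- pred$status %in% c("classified", "unclassified")
  cls <- pred$status == "classified"
  n_eval <- sum(eligible)
  if (sum(cls) == 0) {
    warning("evaluate_demux: no classified reads; metrics undefined")
  }
  acc <- if (sum(cls) > 0) mean(pred$predicted[cls] == truth[cls]) else NA
  labs <- sort(setdiff(unique(c(truth[eligible], pred$predicted[cls])),
                       "NOISE"))
  per_class <- lapply(labs, function(l) {
    tp <- sum(cls & pred$predicted == l & truth == l)
    fp <- sum(cls & pred$predicted == l & truth != l)
    fn <- sum(cls & pred$predicted != l & truth == l)
    tibble::tibble(label = l,
                   precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   n_true = sum(truth[eligible] == l))
  })
  per_class <- dplyr::bind_rows(per_class)
  cm <- NULL
  if (sum(cls) > 0) {
    cm <- table(truth = factor(truth[cls], levels = labs),
                predicted = factor(pred$predicted[cls], levels = labs))
    cm <- prop.table(cm + 0, margin = 1)
  }
  curve <- dplyr::bind_rows(lapply(cutoff_grid, function(cut) {
    keep <- eligible & !is.na(pred$confidence) & pred$confidence >= cut
    tibble::tibble(
      cutoff = cut,
      n_classified = sum(keep),
      classified_fraction = sum(keep) / max(1, n_eval),
      accuracy = if (sum(keep) > 0) {
        mean(pred$predicted[keep] == truth[keep])
      } else NA_real_)
  }))
  structure(list(accuracy = acc,
                 unclassified_fraction = sum(pred$status == "unclassified") /
                   max(1, n_eval),
                 noise_fraction = mean(pred$status == "noise"),
                 qc_fail_fraction = mean(pred$status == "qc_fail"),
                 n_classified = sum(cls),
                 per_class = per_class,
                 macro_precision = mean(per_class$precision, na.rm = TRUE),
                 macro_recall = mean(per_class$recall, na.rm = TRUE),
                 confusion = cm,
                 curve = curve),
            class = "demux_eval")
}

#' @export
print.demux_eval <- function(x, ...) {
  cat("<demux_eval> accuracy:", format(x$accuracy, digits = 4),
      " unclassified:", format(x$unclassified_fraction, digits = 3),
      " noise:", format(x$noise_fraction, digits = 3), "\n")
  cat("  macro precision:", format(x$macro_precision, digits = 4),
      " macro recall:", format(x$macro_recall, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.demux_eval <- function(x, ...) x$per_class

#' @export
glance.demux_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 unclassified_fraction = x$unclassified_fraction,
                 noise_fraction = x$noise_fraction,
                 qc_fail_fraction = x$qc_fail_fraction,
                 n_classified = x$n_classified)
}

#' @export
autoplot.demux_eval <- function(object, type = c("confusion", "curve"),
                                ...) {
  type <- match.arg(type)
  if (type == "confusion") {
    df <- as.data.frame(object$confusion)
    ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                     fill = .data$Freq)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$Freq)),
                         size = 2.5) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                   limits = c(0, 1)) +
      ggplot2::labs(x = "Predicted", y = "True",
                    fill = "Recall", title = "Confusion (recall-normalized)")
  } else {
    ggplot2::ggplot(object$curve,
                    ggplot2::aes(.data$classified_fraction,
                                 .data$accuracy)) +
      ggplot2::geom_path(colour = "steelblue") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$cutoff)) +
      ggplot2::labs(x = "Classified fraction (yield)", y = "Accuracy",
                    colour = "Cutoff",
                    title = "Accuracy-yield trade-off")
  }
}

#' Save a demultiplexer model archive
#'
#' Writes a directory with versioned JSON metadata (`model.json`), the
#' support fingerprints and labels as TSV, and the fitted SVM state.
#'
#' @param model A `demux_model`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_demux_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = model$format_version,
               classes = model$classes,
               gamma = model$dtw_cfg$gamma,
               window = model$dtw_cfg$window,
               C = model$C, seed = model$seed,
               fingerprint_len = model$fingerprint_len,
               n_train = nrow(model$fingerprints))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  fp <- as.data.frame(model$fingerprints)
  names(fp) <- sprintf("f%02d", seq_len(ncol(fp)))
  fp <- cbind(label = model$labels, fp)
  utils::write.table(fp, file.path(dir, "fingerprints.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # the TSV above is for interoperability; predictions must round-trip
  # bit-identically, so the numeric state is stored losslessly as well
  saveRDS(list(pair_models = model$pair_models,
               fingerprints = model$fingerprints,
               labels = model$labels),
          file.path(dir, "svm_state.rds"))
  invisible(dir)
}

#' Load a demultiplexer model archive
#'
#' @param dir Directory written by [save_demux_model()].
#' @return A `demux_model` whose predictions are bit-identical to the
#'   saved model's.
#' @export
load_demux_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  state <- readRDS(file.path(dir, "svm_state.rds"))
  pair_models <- state$pair_models
  structure(list(fingerprints = state$fingerprints,
                 labels = state$labels,
                 classes = meta$classes,
                 dtw_cfg = dtw_config(window = meta$window,
                                      gamma = meta$gamma),
                 C = meta$C, seed = meta$seed,
                 fingerprint_len = meta$fingerprint_len,
                 n_folds = meta$n_folds,
                 pair_models = pair_models,
                 format_version = meta$format_version),
            class = "demux_model")
}
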