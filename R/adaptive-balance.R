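#' Stream a read set as fixed-duration chunks
#'
#' Emulates the chunked delivery of raw signal during sequencing: reads are
#' shuffled, assigned round-robin to channels, and each read's signal is cut
#' into chunks of `chunk_ms` milliseconds (the last chunk carries the
#' remainder). Chunks are emitted in simulated time order; within a channel,
#' per-read chunk order is preserved.
#'
#' @param reads Read tibble with `signal` list column and `sample_rate`.
#' @param chunk_ms Chunk duration in milliseconds (default 100, roughly 300
#'   samples at 3012 Hz).
#' @param n_channels Number of parallel channels (default 1).
#' @param seed Integer seed for the read shuffle.
#' @return A tibble with columns `channel`, `read_id`, `read_serial` (order
#'   within channel), `chunk_idx`, `samples` (list), `is_read_start`,
#'   `is_read_end`, ordered by simulated emission time.
#' @export
stream_reads <- function(reads, chunk_ms = 100, n_channels = 1, seed = 1) {
  if (nrow(reads) == 0) stop("stream_reads: empty dataset")
  withr_seed(seed, {
    ord <- sample(nrow(reads))
    reads <- reads[ord, ]
    channel <- rep_len(seq_len(n_channels), nrow(reads))
    rows <- lapply(seq_len(nrow(reads)), function(i) {
      sig <- reads$signal[[i]]
      chunk_len <- max(1L, as.integer(round(chunk_ms *
                                              reads$sample_rate[i] / 1000)))
      starts <- seq(1L, length(sig), by = chunk_len)
      nck <- length(starts)
      tibble::tibble(
        channel = channel[i],
        read_id = reads$read_id[i],
        chunk_idx = seq_len(nck),
        samples = lapply(seq_len(nck), function(j) {
          sig[starts[j]:min(length(sig), starts[j] + chunk_len - 1L)]
        }),
        is_read_start = seq_len(nck) == 1L,
        is_read_end = seq_len(nck) == nck)
    })
    chunks <- dplyr::bind_rows(rows)
    chunks <- chunks |>
      dplyr::group_by(.data$channel) |>
      dplyr::mutate(read_serial = cumsum(.data$is_read_start),
                    tick = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$tick, .data$channel) |>
      dplyr::select("channel", "read_id", "read_serial", "chunk_idx",
                    "samples", "is_read_start", "is_read_end")
    chunks
  })
}

#' Classify a read from streamed chunks
#'
#' Accumulates chunks and, after each one, searches the accumulated prefix
#' for the poly(A) onset (with a reduced plateau-evidence requirement of
#' `live_polya_samples`, since in live mode only the beginning of the
#' plateau has been seen). On first detection the adapter span is
#' fingerprinted and classified; the total number of samples consumed before
#' the decision is the latency proxy. If no onset is found within
#' `max_samples`, the result is `no_decision`.
#'
#' @param signal Full read signal (numeric) or a list of chunk vectors.
#' @param model A `demux_model`.
#' @param seg_cfg A [seg_config()].
#' @param chunk_samples Chunk size in samples (default 301, 100 ms at
#'   3012 Hz); ignored when `signal` is already a chunk list.
#' @param live_polya_samples Plateau evidence required in live mode
#'   (default 300 samples).
#' @param max_samples Decision budget in samples (default 20000).
#' @param conf_cutoff Confidence cutoff for the returned prediction.
#' @return A list with `prediction` (one-row tibble; `status` is
#'   `"no_decision"` when the budget elapsed) and `samples_consumed`.
#' @export
live_classify <- function(signal, model, seg_cfg = seg_config(),
                          chunk_samples = 301, live_polya_samples = 300,
                          max_samples = 20000, conf_cutoff = 0) {
  chunks <- if (is.list(signal)) signal else {
    starts <- seq(1L, length(signal), by = chunk_samples)
    lapply(starts, function(s) {
      signal[s:min(length(signal), s + chunk_samples - 1L)]
    })
  }
  cfg_live <- seg_cfg
  cfg_live$min_polya_samples <- as.integer(live_polya_samples)
  acc <- numeric(0)
  for (ck in chunks) {
    acc <- c(acc, ck)
    if (length(acc) < 10 * cfg_live$tstat_window) next
    bd <- detect_boundaries(acc, cfg_live)
    if (bd$ok) {
      fp <- extract_fingerprint(acc, cfg_live)
      fps <- tibble::tibble(read_id = "live", fingerprint = list(fp$values),
                            ok = fp$ok)
      pred <- predict(model, fps, conf_cutoff = conf_cutoff)
      return(list(prediction = pred, samples_consumed = length(acc)))
    }
    if (length(acc) >= max_samples) break
  }
  pred <- tibble::tibble(read_id = "live", predicted = NA_character_,
                         confidence = NA_real_, status = "no_decision")
  list(prediction = pred, samples_consumed = min(length(acc), max_samples))
}

#' Initialize a barcode-balancer state
#'
#' Live per-barcode tallies (adapters, reads, bases) with a dynamic
#' rejection rule: a barcode is rejected when it leads the tally on the
#' chosen metric by more than `slack` times the largest tally among the
#' other barcodes already seen.
#'
#' @param barcodes Character vector of barcode labels handled by the model
#'   (without `NOISE`).
#' @param metric `"read_count"` (default), `"adapter_count"` or
#'   `"base_count"`.
#' @param slack Dynamic-threshold slack ratio > 1 (default 1.2).
#' @return A list of class `balancer_state`.
#' @export
balancer_state <- function(barcodes,
                           metric = c("read_count", "adapter_count",
                                      "base_count"),
                           slack = 1.2) {
  metric <- match.arg(metric)
  stopifnot(slack > 1, length(barcodes) >= 1)
  zero <- setNames(rep(0, length(barcodes)), barcodes)
  structure(list(barcodes = barcodes, metric = metric, slack = slack,
                 adapters = zero, reads = zero, bases = zero,
                 n_decisions = 0L),
            class = "balancer_state")
}

metric_tally <- function(state) {
  switch(state$metric,
         adapter_count = state$adapters,
         read_count = state$reads,
         base_count = state$bases)
}

#' Take an accept/reject decision for one classified read
#'
#' Unclassified, noise, QC-failed or no-decision reads are always accepted:
#' the balancer cannot act on an unknown identity, and a conservative
#' default ensures misclassification never silently discards a sample.
#' Otherwise the read is rejected iff its barcode currently leads the
#' tally on the balance metric by more than the slack ratio: `tally[b] >
#' slack * max(tally of the other barcodes already seen)`. Trimming the
#' leader is robust to stray labels with token tallies (from occasional
#' misclassifications), which would drag down a mean-based threshold until
#' it fires on every active barcode. Tallies are updated after the
#' decision, so the threshold is dynamic and recomputed at every call.
#'
#' @param state A [balancer_state()].
#' @param barcode Predicted barcode label (may be NA for non-classified).
#' @param status Prediction status string.
#' @param confidence Prediction confidence.
#' @param conf_cutoff Confidence needed to act on a classification.
#' @param read_bases Estimated base count credited on acceptance.
#' @param adapter_only If `TRUE` the accepted read is adapter-only sequencer
#'   output: the adapter tally is credited but reads/bases are not
#'   (tally correction against actual output).
#' @return A list with `decision` (`"accept"`/`"reject"`/`"no_decision"`)
#'   and the updated `state`.
#' @export
decide <- function(state, barcode, status, confidence = 1, conf_cutoff = 0,
                   read_bases = 0, adapter_only = FALSE) {
  actionable <- identical(status, "classified") &&
    !is.na(confidence) && confidence >= conf_cutoff
  if (actionable && !barcode %in% state$barcodes) {
    stop("decide: unknown barcode label ", barcode)
  }
  decision <- "accept"
  if (actionable) {
    tal <- metric_tally(state)
    others <- tal[names(tal) != barcode]
    others <- others[others > 0]
    if (length(others) > 0 && tal[barcode] > state$slack * max(others)) {
      decision <- "reject"
    }
    state$adapters[barcode] <- state$adapters[barcode] + 1
    if (decision == "accept" && !adapter_only) {
      state$reads[barcode] <- state$reads[barcode] + 1
      state$bases[barcode] <- state$bases[barcode] + read_bases
    }
  }
  state$n_decisions <- state$n_decisions + 1L
  list(decision = decision, state = state)
}

#' Gini coefficient of a count vector
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`; 0 for perfectly balanced
#' counts, approaching 1 under extreme concentration. Scale-invariant.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @return A number in `[0, 1)`.
#' @examples
#' gini(c(0, 0, 0, 100)) # 0.75
#' @export
gini <- function(counts) {
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) stop("gini: all counts are zero")
  n <- length(counts)
  sum(abs(outer(counts, counts, "-"))) / (2 * n^2 * mean(counts))
}

#' Simulate a barcode-balancing sequencing run
#'
#' Replays a read set through parallel channels under a fixed
#' sequencing-time budget. Accepting a read occupies its channel for the
#' full read duration; rejecting frees the channel after only the samples
#' consumed up to the decision plus a rejection penalty (the voltage-flip
#' and pore-clearance proxy), so rejection of over-represented barcodes
#' buys time for under-represented ones. A configurable fraction of reads
#' is treated as adapter-only library artifacts: they are classified and
#' counted as adapters, but produce no sequencer read output, and the
#' balancer corrects its read/base tallies accordingly.
#'
#' @param reads Read tibble with truth `label` column.
#' @param predictions Prediction tibble aligned with `reads` (e.g. from
#'   [predict.demux_model()] on the extracted fingerprints); the per-read
#'   decision latency is taken as the detected/true poly(A) onset.
#' @param balancing Apply the rejection rule (`TRUE`) or accept everything
#'   (`FALSE`, control).
#' @param metric,slack See [balancer_state()].
#' @param conf_cutoff Confidence needed to act on a classification.
#' @param n_channels Parallel channels (default 8).
#' @param time_budget_s Sequencing time budget per channel in seconds;
#'   default half the time needed to sequence everything, so the control
#'   run cannot finish the queue.
#' @param rejection_penalty_s Channel time lost per rejection (default 0.5).
#' @param decision_extra_samples Samples consumed past the poly(A) onset
#'   before the decision (default 600, about two 100 ms chunks).
#' @param adapter_only_fraction Fraction of reads emulated as adapter-only
#'   output (default 0.05).
#' @param translocation_speed Motor speed in nt/s used to convert accepted
#'   samples into an estimated base tally (default 70).
#' @param seed Integer seed (read order and adapter-only assignment).
#' @return An object of class `balance_report`: per-barcode accepted read
#'   counts, the Gini coefficient over them, and the full decision log.
#' @export
run_balancing_experiment <- function(reads, predictions, balancing = TRUE,
                                     metric = "read_count", slack = 1.2,
                                     conf_cutoff = 0, n_channels = 8,
                                     time_budget_s = NULL,
                                     rejection_penalty_s = 0.5,
                                     decision_extra_samples = 600,
                                     adapter_only_fraction = 0.05,
                                     translocation_speed = 70,
                                     seed = 1) {
  stopifnot(nrow(reads) == nrow(predictions))
  barcodes <- sort(setdiff(unique(reads$label), "NOISE"))
  # the balancer must know every label the classifier can emit, not just
  # the barcodes present in this dataset
  state_barcodes <- sort(setdiff(
    unique(c(barcodes, predictions$predicted[!is.na(predictions$predicted)])),
    "NOISE"))
  read_len <- lengths(reads$signal)
  rate <- reads$sample_rate[1]
  onset <- ifelse(is.na(reads$adapter_end), pmin(read_len, 5000),
                  reads$adapter_end)
  if (is.null(time_budget_s)) {
    time_budget_s <- 0.5 * sum(read_len) / rate / n_channels
  }
  withr_seed(seed, {
    ord <- sample(nrow(reads))
    adapter_only <- runif(nrow(reads)) < adapter_only_fraction
    state <- balancer_state(state_barcodes, metric = metric, slack = slack)
    ch_time <- rep(0, n_channels)
    n <- length(ord)
    lg_channel <- integer(n)
    lg_decision <- character(n)
    lg_consumed <- numeric(n)
    lg_time <- numeric(n)
    counts <- setNames(rep(0, length(barcodes)), barcodes)
    done <- 0L
    for (pos in seq_along(ord)) {
      i <- ord[pos]
      ch <- which.min(ch_time)
      if (ch_time[ch] >= time_budget_s) break
      consumed_at_decision <- min(read_len[i],
                                  onset[i] + decision_extra_samples)
      if (balancing) {
        est_bases <- read_len[i] * translocation_speed / rate
        dec <- decide(state, predictions$predicted[i],
                      predictions$status[i], predictions$confidence[i],
                      conf_cutoff, read_bases = est_bases,
                      adapter_only = adapter_only[i])
        state <- dec$state
        decision <- dec$decision
      } else {
        decision <- "accept"
      }
      if (decision == "accept") {
        dt <- read_len[i] / rate
        lg_consumed[pos] <- read_len[i]
      } else {
        dt <- consumed_at_decision / rate + rejection_penalty_s
        lg_consumed[pos] <- consumed_at_decision
      }
      if (decision == "accept" && !adapter_only[i] &&
          reads$label[i] %in% barcodes) {
        counts[reads$label[i]] <- counts[reads$label[i]] + 1
      }
      lg_channel[pos] <- ch
      lg_decision[pos] <- decision
      lg_time[pos] <- ch_time[ch] + dt
      ch_time[ch] <- ch_time[ch] + dt
      done <- pos
    }
    keep <- seq_len(done)
    idx <- ord[keep]
    log <- tibble::tibble(
      read_id = reads$read_id[idx], channel = lg_channel[keep],
      true_label = reads$label[idx],
      predicted = predictions$predicted[idx],
      status = predictions$status[idx],
      confidence = predictions$confidence[idx],
      decision = lg_decision[keep], adapter_only = adapter_only[idx],
      samples_consumed = lg_consumed[keep],
      channel_time_s = lg_time[keep])
    structure(list(counts = counts, gini = gini(counts),
                   balancing = balancing, metric = metric, slack = slack,
                   n_channels = n_channels, time_budget_s = time_budget_s,
                   state = state, log = log),
              class = "balance_report")
  })
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report>", if (x$balancing) "balanced" else "control",
      "run;", nrow(x$log), "decisions; Gini =", format(x$gini, digits = 3),
      "\n")
  print(x$counts)
  invisible(x)
}

#' @export
glance.balance_report <- function(x, ...) {
  tibble::tibble(balancing = x$balancing, gini = x$gini,
                 n_decisions = nrow(x$log),
                 n_rejected = sum(x$log$decision == "reject"),
                 min_count = min(x$counts), total_reads = sum(x$counts))
}

#' @export
tidy.balance_report <- function(x, ...) {
  tibble::tibble(barcode = names(x$counts), reads = unname(x$counts))
}

#' Compare balanced and control runs
#'
#' Runs [run_balancing_experiment()] twice under a matched seed and budget,
#' with and without the rejection rule, and summarizes the balancing
#' effect: Gini before/after and the enrichment of the least abundant
#' barcode.
#'
#' @inheritParams run_balancing_experiment
#' @return A list with both reports and a one-row `summary` tibble
#'   (`gini_control`, `gini_balanced`, `min_count_control`,
#'   `min_count_balanced`, `low_abundance_enrichment`).
#' @export
balancing_comparison <- function(reads, predictions, metric = "read_count",
                                 slack = 1.2, conf_cutoff = 0,
                                 n_channels = 8, time_budget_s = NULL,
                                 rejection_penalty_s = 0.5,
                                 adapter_only_fraction = 0.05, seed = 1) {
  if (is.null(time_budget_s)) {
    time_budget_s <- 0.5 * sum(lengths(reads$signal)) /
      reads$sample_rate[1] / n_channels
  }
  ctrl <- run_balancing_experiment(reads, predictions, balancing = FALSE,
                                   metric = metric, slack = slack,
                                   conf_cutoff = conf_cutoff,
                                   n_channels = n_channels,
                                   time_budget_s = time_budget_s,
                                   rejection_penalty_s = rejection_penalty_s,
                                   adapter_only_fraction =
                                     adapter_only_fraction, seed = seed)
  bal <- run_balancing_experiment(reads, predictions, balancing = TRUE,
                                  metric = metric, slack = slack,
                                  conf_cutoff = conf_cutoff,
                                  n_channels = n_channels,
                                  time_budget_s = time_budget_s,
                                  rejection_penalty_s = rejection_penalty_s,
                                  adapter_only_fraction =
                                    adapter_only_fraction, seed = seed)
  rare <- names(which.min(ctrl$counts))
  enr <- if (ctrl$counts[rare] > 0) {
    bal$counts[rare] / ctrl$counts[rare] - 1
  } else NA_real_
  list(control = ctrl, balanced = bal,
       summary = tibble::tibble(
         gini_control = ctrl$gini, gini_balanced = bal$gini,
         min_count_control = min(ctrl$counts),
         min_count_balanced = min(bal$counts),
         low_abundance_enrichment = unname(enr)))
}
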