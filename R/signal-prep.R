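#' Segmentation and fingerprinting configuration
#'
#' Controls adapter/poly(A) boundary detection, event segmentation and the
#' barcode fingerprint. The adapter is deliberately over-segmented by about
#' 10% relative to its expected base count to avoid losing events, and only
#' the last `fingerprint_len` segments - the temporal tail of the adapter,
#' which carries the barcode - are retained after normalization.
#'
#' @param expected_adapter_bases Expected number of adapter bases (default
#'   50; tunable, the true RTA base count is not documented).
#' @param overseg_factor Over-segmentation ratio (default 1.10), so the
#'   adapter is cut into `round(expected_adapter_bases * overseg_factor)`
#'   segments.
#' @param tstat_window Half-window in samples for the Welch t-statistic used
#'   to rank candidate changepoints.
#' @param min_seg_len Minimum segment length in samples.
#' @param fingerprint_len Number of trailing segments kept as the
#'   fingerprint (default 25).
#' @param normalization `"median_mad"` (robust, default) or `"zscore"`.
#' @param polya_window Sliding-window width (samples) for plateau search.
#' @param polya_band Current band within which the poly(A) plateau level
#'   must fall.
#' @param polya_var_mult Multiplier on the 5% quantile of the rolling
#'   variance that sets the low-variance threshold for plateau candidates.
#' @param min_polya_samples Minimum plateau length in samples.
#' @param min_adapter_samples Minimum adapter length in samples.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(expected_adapter_bases = 50,
                       overseg_factor = 1.10,
                       tstat_window = 15,
                       min_seg_len = 3,
                       fingerprint_len = 25,
                       normalization = c("median_mad", "zscore"),
                       polya_window = 200,
                       polya_band = c(95, 125),
                       polya_var_mult = 4,
                       min_polya_samples = 500,
                       min_adapter_samples = 300) {
  normalization <- match.arg(normalization)
  n_segments <- as.integer(round(expected_adapter_bases * overseg_factor))
  if (fingerprint_len > n_segments) {
    stop("seg_config: fingerprint_len must not exceed the segment count ",
         n_segments)
  }
  structure(list(expected_adapter_bases = as.integer(expected_adapter_bases),
                 overseg_factor = overseg_factor,
                 tstat_window = as.integer(tstat_window),
                 min_seg_len = as.integer(min_seg_len),
                 fingerprint_len = as.integer(fingerprint_len),
                 normalization = normalization,
                 n_segments = n_segments,
                 polya_window = as.integer(polya_window),
                 polya_band = polya_band,
                 polya_var_mult = polya_var_mult,
                 min_polya_samples = as.integer(min_polya_samples),
                 min_adapter_samples = as.integer(min_adapter_samples)),
            class = "seg_config")
}

rolling_mean_var <- function(x, w) {
  n <- length(x)
  s <- cumsum(c(0, x))
  s2 <- cumsum(c(0, x^2))
  idx <- seq_len(n - w + 1)
  m <- (s[idx + w] - s[idx]) / w
  v <- pmax(0, (s2[idx + w] - s2[idx]) / w - m^2)
  list(mean = m, var = v)
}

# two-segment mean-shift LLR refinement: argmax over split t of
# n1*n2/n * (mean_left - mean_right)^2 within x; returns t (samples left of
# the changepoint), ties broken by the lower index
llr_changepoint <- function(x) {
  n <- length(x)
  if (n < 2) return(1L)
  s <- cumsum(x)
  t <- seq_len(n - 1)
  m1 <- s[t] / t
  m2 <- (s[n] - s[t]) / (n - t)
  score <- (t * (n - t) / n) * (m1 - m2)^2
  which.max(score)
}

#' Locate the adapter/poly(A) boundary in a raw signal
#'
#' Finds the poly(A) plateau as the longest low-variance stretch whose level
#' lies inside `polya_band`, then refines its onset by maximizing a
#' two-segment mean-shift log-likelihood-ratio statistic around the
#' candidate start. Never raises an error for a missing plateau; the failure
#' is reported through `qc_flags` so the read can be routed to the noise or
#' unclassified path downstream.
#'
#' @param read A numeric signal vector or a one-row read tibble with a
#'   `signal` list column.
#' @param cfg A [seg_config()].
#' @return A list with `adapter_start` (1), `adapter_end` (number of adapter
#'   samples = poly(A) onset), `polya_end` (last plateau sample), `ok`, and
#'   a character vector `qc_flags`.
#' @export
detect_boundaries <- function(read, cfg = seg_config()) {
  sig <- if (is.data.frame(read)) read$signal[[1]] else as.numeric(read)
  n <- length(sig)
  w <- cfg$polya_window
  fail <- function(flags) list(adapter_start = 1L, adapter_end = NA_integer_,
                               polya_end = NA_integer_, ok = FALSE,
                               qc_flags = flags)
  if (n < 10 * cfg$tstat_window || n < w + 2) return(fail("too_short"))
  rv <- rolling_mean_var(sig, w)
  # the minimum rolling variance estimates the measurement-noise floor
  # (within-event variance) without assuming how much of the signal is
  # plateau, so the same rule works on full reads and on streamed prefixes
  thresh <- cfg$polya_var_mult * min(rv$var) + 1e-9
  cand <- rv$var <= thresh &
    rv$mean >= cfg$polya_band[1] & rv$mean <= cfg$polya_band[2]
  runs <- rle(cand)
  if (!any(runs$values)) return(fail("no_polya"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # run i covers window starts [starts[i], ends[i]]; plateau samples span
  # [starts[i], ends[i] + w - 1]
  lens <- runs$lengths + w - 1
  lens[!runs$values] <- 0L
  best <- which.max(lens)
  if (lens[best] < cfg$min_polya_samples) return(fail("no_polya"))
  p_start <- starts[best]
  p_end <- min(n, ends[best] + w - 1)
  # refine the onset in a tight window straddling the coarse plateau start;
  # the coarse start is within a few boundary samples of the true onset, and
  # a tight window keeps adapter-internal event boundaries out of the LLR
  half <- max(16L, as.integer(0.3 * w))
  a <- max(1, p_start - half)
  b <- min(n, p_start + half)
  t <- llr_changepoint(sig[a:b])
  adapter_end <- a + t - 1
  flags <- character(0)
  if (adapter_end < cfg$min_adapter_samples) flags <- c(flags, "short_adapter")
  list(adapter_start = 1L, adapter_end = as.integer(adapter_end),
       polya_end = as.integer(p_end), ok = length(flags) == 0,
       qc_flags = flags)
}

#' Segment a signal slice into events
#'
#' Computes a Welch t-statistic between adjacent windows of `tstat_window`
#' samples at every interior position (windows clipped at the slice ends),
#' then greedily keeps the `n_segments - 1` highest-t positions subject to a
#' `min_seg_len` spacing constraint, descending t, ties broken by the lower
#' index. If the greedy pass cannot place enough boundaries, the remaining
#' ones are inserted deterministically at midpoints of the largest gaps. The
#' segments partition the slice exactly.
#'
#' @param x Numeric signal slice.
#' @param n_segments Number of segments to produce.
#' @param cfg A [seg_config()].
#' @return Numeric vector of segment means, with attributes `boundaries`
#'   (cut positions: segment i spans `(boundaries[i], boundaries[i+1]]`) and
#'   `lengths`.
#' @export
segment_adapter <- function(x, n_segments, cfg = seg_config()) {
  n <- length(x)
  msl <- cfg$min_seg_len
  if (n < n_segments * msl) {
    stop("segment_adapter: slice of length ", n, " too short; need >= ",
         n_segments * msl, " samples")
  }
  if (n_segments == 1) {
    return(structure(mean(x), boundaries = c(0L, n), lengths = n))
  }
  w <- cfg$tstat_window
  s <- cumsum(c(0, x))
  s2 <- cumsum(c(0, x^2))
  t_pos <- seq_len(n - 1)
  lo <- pmax(0, t_pos - w)
  hi <- pmin(n, t_pos + w)
  n1 <- t_pos - lo
  n2 <- hi - t_pos
  m1 <- (s[t_pos + 1] - s[lo + 1]) / n1
  m2 <- (s[hi + 1] - s[t_pos + 1]) / n2
  v1 <- pmax(0, (s2[t_pos + 1] - s2[lo + 1]) / n1 - m1^2)
  v2 <- pmax(0, (s2[hi + 1] - s2[t_pos + 1]) / n2 - m2^2)
  tstat <- abs(m1 - m2) / sqrt(v1 / pmax(1, n1 - 1) + v2 / pmax(1, n2 - 1) +
                                 1e-12)
  allowed <- t_pos >= msl & t_pos <= n - msl
  ord <- order(-tstat[allowed], t_pos[allowed])
  cand <- t_pos[allowed][ord]
  kept <- integer(0)
  need <- n_segments - 1
  for (p in cand) {
    if (length(kept) == need) break
    if (all(abs(kept - p) >= msl)) kept <- c(kept, p)
  }
  while (length(kept) < need) {
    cuts <- sort(c(0L, kept, n))
    gaps <- diff(cuts)
    g <- which.max(gaps)
    if (gaps[g] < 2 * msl) break
    kept <- c(kept, cuts[g] + gaps[g] %/% 2L)
  }
  cuts <- sort(c(0L, kept, n))
  lens <- diff(cuts)
  means <- (s[cuts[-1] + 1] - s[cuts[-length(cuts)] + 1]) / lens
  structure(means, boundaries = cuts, lengths = lens)
}

#' Normalize segment means
#'
#' `median_mad`: `(x - median) / (MAD * 1.4826)` with the raw (unscaled)
#' median absolute deviation, the 1.4826 factor making the scale consistent
#' with a Gaussian sd; robust to the outlier spikes that noise reads carry.
#' Falls back to z-scoring when the MAD is zero, and to all zeros when the
#' sd is also zero. Both methods are invariant under positive affine
#' transformations of the input, and idempotent up to numerical precision.
#'
#' @param x Numeric vector (>= 2 values).
#' @param method `"median_mad"` or `"zscore"`.
#' @return Normalized numeric vector of the same length.
#' @export
normalize_segments <- function(x, method = c("median_mad", "zscore")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 2)
  if (method == "median_mad") {
    m <- median(x)
    md <- median(abs(x - m))
    if (md > 0) return((x - m) / (md * 1.4826))
    method <- "zscore"
  }
  s <- sd(x)
  if (s == 0 || !is.finite(s)) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Extract the barcode fingerprint of one read
#'
#' Runs boundary detection, segments the adapter span into
#' `round(expected_adapter_bases * overseg_factor)` events, normalizes over
#' all segments, and returns the last `fingerprint_len` normalized segment
#' means. Boundary or length failures are reported via `ok`/`qc_flags`, not
#' as errors.
#'
#' @param read A numeric signal vector or one-row read tibble.
#' @param cfg A [seg_config()].
#' @return A list with `values` (numeric `fingerprint_len` vector or NULL),
#'   `ok`, `qc_flags`, and the detected `boundaries`.
#' @export
extract_fingerprint <- function(read, cfg = seg_config()) {
  sig <- if (is.data.frame(read)) read$signal[[1]] else as.numeric(read)
  bd <- detect_boundaries(sig, cfg)
  if (!bd$ok) {
    return(list(values = NULL, ok = FALSE, qc_flags = bd$qc_flags,
                boundaries = bd))
  }
  slice <- sig[seq_len(bd$adapter_end)]
  if (length(slice) < cfg$n_segments * cfg$min_seg_len) {
    return(list(values = NULL, ok = FALSE,
                qc_flags = c(bd$qc_flags, "short_adapter"), boundaries = bd))
  }
  segs <- segment_adapter(slice, cfg$n_segments, cfg)
  norm <- normalize_segments(as.numeric(segs), cfg$normalization)
  vals <- norm[(length(norm) - cfg$fingerprint_len + 1):length(norm)]
  list(values = vals, ok = TRUE, qc_flags = bd$qc_flags, boundaries = bd)
}

#' Fingerprint a table of reads
#'
#' Tidy wrapper around [extract_fingerprint()]: one row in, one row out,
#' with the fingerprint as a list column. Failed reads keep a `NULL`
#' fingerprint and `ok = FALSE` so they can be routed to the unclassified
#' path rather than dropped silently.
#'
#' @param reads A read tibble (see [simulate_dataset()] / [read_signals()]).
#' @param cfg A [seg_config()].
#' @return A tibble with columns `read_id`, `fingerprint` (list), `ok`,
#'   `qc_flags`, and `label` / `replicate_id` carried through when present.
#' @export
extract_fingerprints <- function(reads, cfg = seg_config()) {
  fps <- lapply(seq_len(nrow(reads)), function(i) {
    extract_fingerprint(reads$signal[[i]], cfg)
  })
  out <- tibble::tibble(
    read_id = reads$read_id,
    fingerprint = lapply(fps, `[[`, "values"),
    ok = vapply(fps, `[[`, logical(1), "ok"),
    qc_flags = vapply(fps, function(f) {
      paste(f$qc_flags, collapse = ",")
    }, character(1))
  )
  for (col in c("label", "replicate_id")) {
    if (col %in% names(reads)) out[[col]] <- reads[[col]]
  }
  out
}

# stack the fingerprints of a fingerprint tibble into a matrix (ok rows only)
fingerprint_matrix <- function(fps) {
  stopifnot(all(fps$ok))
  do.call(rbind, fps$fingerprint)
}
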