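#' Robust Z-scores
#'
#' `(x - median(x)) / MAD` with `MAD = median(|x - median(x)|)` (raw,
#' unscaled). When the MAD is zero all scores are defined as 0 (degenerate
#' convention). Translation-invariant by construction.
#'
#' @param x Numeric vector (>= 2 finite values).
#' @return Numeric vector of robust Z-scores.
#' @examples
#' robust_zscore(c(1, 2, 3, 4, 100)) # the outlier scores 97
#' @export
robust_zscore <- function(x) {
  if (anyNA(x) || !all(is.finite(x))) stop("robust_zscore: non-finite input")
  stopifnot(length(x) >= 2)
  m <- median(x)
  md <- median(abs(x - m))
  if (md == 0) return(rep(0, length(x)))
  (x - m) / md
}

#' Select noise-class training instances
#'
#' For every read, computes the median DTW distance to (a capped random
#' sample of) reads of the *other* barcode classes, then robust-Z-scores
#' these medians across the dataset. Reads far from every class - signal
#' irregularities such as stalled adapters or bad boundaries - stand out
#' with large scores. The top `n_noise` reads with score above `z_cutoff`
#' are returned (fewer when the cutoff filters more). The selection is
#' invariant to the ordering of the input rows.
#'
#' @param fps Fingerprint tibble with `fingerprint` (list) and `label`
#'   columns; all rows must have `ok = TRUE` fingerprints.
#' @param n_noise Maximum number of instances to select (default 400).
#' @param z_cutoff Robust-Z threshold (default 3.5, the classical robust
#'   outlier convention).
#' @param ref_cap Maximum other-class reads sampled per read (default 200).
#' @param dtw_cfg A [dtw_config()].
#' @param seed Integer seed for the reference subsampling.
#' @return Integer row indices into `fps`, ordered by decreasing score, with
#'   attribute `scores` (all reads' robust Z-scores).
#' @export
select_noise_instances <- function(fps, n_noise = 400, z_cutoff = 3.5,
                                   ref_cap = 200, dtw_cfg = dtw_config(),
                                   seed = 1) {
  if (n_noise > nrow(fps)) {
    stop("select_noise_instances: n_noise exceeds the dataset size")
  }
  if (length(unique(fps$label)) < 2) {
    stop("select_noise_instances: need at least two barcode classes")
  }
  series <- fps$fingerprint
  lab <- fps$label
  # stable per-read order so the scores do not depend on row permutation:
  # sample references in read_id order
  X <- withr_seed(seed, {
    ord <- order(fps$read_id)
    med <- numeric(nrow(fps))
    for (i in ord) {
      other <- which(lab != lab[i])
      other <- other[order(fps$read_id[other])]
      if (length(other) > ref_cap) other <- other[sample(length(other),
                                                         ref_cap)]
      d <- pairwise_dtwd(series[i], series[other], dtw_cfg)
      med[i] <- median(as.numeric(d))
    }
    med
  })
  z <- robust_zscore(X)
  ord <- order(-z, fps$read_id)
  keep <- ord[z[ord] > z_cutoff]
  structure(head(keep, n_noise), scores = z)
}

greedy_diversity <- function(D, k, maximize = TRUE) {
  M <- nrow(D)
  stopifnot(k <= M)
  if (k == 0) return(integer(0))
  if (!maximize) D <- -D
  if (k == 1) return(1L)
  Dx <- D
  diag(Dx) <- -Inf
  ij <- arrayInd(which.max(Dx), dim(Dx))
  sel <- sort(c(ij[1], ij[2]))
  while (length(sel) < k) {
    rest <- setdiff(seq_len(M), sel)
    gain <- colSums(D[sel, rest, drop = FALSE])
    sel <- c(sel, rest[which.max(gain)])
  }
  sel
}

#' Diversity-stratified training subsample
#'
#' Per barcode class, selects `n_max_div` instances by greedy maximal
#' diversity on the within-class DTW distance matrix (the same greedy as
#' [solve_mdp()]), `n_min_div` by the mirrored greedy *minimal* diversity
#' from the remainder (seeded from the globally closest pair), and
#' `n_random` uniformly at random from the rest - capturing the extremes
#' and the bulk of each class's signal distribution with a small training
#' set. When a `replicate_id` column is present the random stratum is
#' drawn (approximately) evenly across replicates.
#'
#' @param fps Fingerprint tibble with `fingerprint` and `label` columns.
#' @param n_max_div,n_min_div,n_random Per-class stratum sizes (defaults
#'   80 / 80 / 240, totalling 400).
#' @param dtw_cfg A [dtw_config()].
#' @param seed Integer seed.
#' @return The selected subset of `fps` rows with an added `stratum` column
#'   (`max_div`, `min_div`, `random`); strata are disjoint and each class
#'   contributes exactly `n_max_div + n_min_div + n_random` rows.
#' @export
diversity_split <- function(fps, n_max_div = 80, n_min_div = 80,
                            n_random = 240, dtw_cfg = dtw_config(),
                            seed = 1) {
  per_class <- n_max_div + n_min_div + n_random
  classes <- unique(fps$label)
  withr_seed(seed, {
    picked <- lapply(classes, function(cl) {
      rows <- which(fps$label == cl)
      if (length(rows) < per_class) {
        stop("diversity_split: class ", cl, " has only ", length(rows),
             " reads; need ", per_class)
      }
      D <- pairwise_dtwd(fps$fingerprint[rows], cfg = dtw_cfg)
      i_max <- greedy_diversity(D, n_max_div, maximize = TRUE)
      rem1 <- setdiff(seq_along(rows), i_max)
      i_min <- rem1[greedy_diversity(D[rem1, rem1, drop = FALSE], n_min_div,
                                     maximize = FALSE)]
      rem2 <- setdiff(seq_along(rows), c(i_max, i_min))
      i_rnd <- if ("replicate_id" %in% names(fps)) {
        stratified_sample(fps$replicate_id[rows[rem2]], rem2, n_random)
      } else {
        sort(sample(rem2, n_random))
      }
      tibble::tibble(row = rows[c(i_max, i_min, i_rnd)],
                     stratum = rep(c("max_div", "min_div", "random"),
                                   c(n_max_div, n_min_div,
                                     length(i_rnd))))
    })
    sel <- dplyr::bind_rows(picked)
    out <- fps[sel$row, ]
    out$stratum <- sel$stratum
    out
  })
}

# draw n items from `idx` spread as evenly as possible across strata
stratified_sample <- function(strata, idx, n) {
  groups <- split(idx, strata)
  groups <- groups[order(names(groups))]
  quota <- rep(n %/% length(groups), length(groups))
  extra <- n %% length(groups)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1
  out <- integer(0)
  short <- 0
  for (g in seq_along(groups)) {
    take <- min(quota[g], length(groups[[g]]))
    short <- short + quota[g] - take
    out <- c(out, sample(groups[[g]], take))
  }
  if (short > 0) {
    rest <- setdiff(idx, out)
    out <- c(out, sample(rest, min(short, length(rest))))
  }
  sort(out)
}

#' Assemble a labeled training set
#'
#' Convenience composition of the training-set recipe: noise instances by
#' robust-Z outlier selection, then a diversity-stratified subsample of
#' each barcode class from the remaining reads.
#'
#' @param fps Fingerprint tibble (ok rows, with `label` ground truth used
#'   only to stratify by class, not to label noise).
#' @param n_noise Noise instances to select (default 400).
#' @param n_max_div,n_min_div,n_random Per-class strata (80/80/240).
#' @param z_cutoff,ref_cap See [select_noise_instances()].
#' @param dtw_cfg A [dtw_config()].
#' @param seed Integer seed.
#' @return A fingerprint tibble with `label` (barcode or `"NOISE"`) and
#'   `stratum` columns.
#' @export
build_training_set <- function(fps, n_noise = 400, n_max_div = 80,
                               n_min_div = 80, n_random = 240,
                               z_cutoff = 3.5, ref_cap = 200,
                               dtw_cfg = dtw_config(), seed = 1) {
  noise_idx <- select_noise_instances(fps, n_noise, z_cutoff, ref_cap,
                                      dtw_cfg, seed)
  noise <- fps[noise_idx, ]
  if (nrow(noise) > 0) {
    noise$label <- "NOISE"
    noise$stratum <- "noise"
  }
  rest <- if (length(noise_idx) > 0) fps[-noise_idx, ] else fps
  div <- diversity_split(rest, n_max_div, n_min_div, n_random, dtw_cfg,
                         seed + 1)
  dplyr::bind_rows(div, noise)
}
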