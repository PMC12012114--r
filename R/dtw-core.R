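#' DTW distance and kernel configuration
#'
#' Settings for the dynamic time warping distance (DTWD) used throughout the
#' package and for the exponential DTW kernel of the classifier,
#' `K(s1, s2) = exp(-gamma * DTWD(s1, s2))`.
#'
#' @param window Sakoe-Chiba band half-width in segments, or `NULL` (default)
#'   for an unconstrained alignment.
#' @param gamma Kernel decay rate (dimensionless, > 0). Default 1.2.
#' @return A list of class `dtw_config`.
#' @export
dtw_config <- function(window = NULL, gamma = 1.2) {
  stopifnot(is.null(window) || (is.numeric(window) && window >= 1))
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0)
  structure(
    list(window = if (is.null(window)) NULL else as.integer(window),
         gamma = gamma),
    class = "dtw_config"
  )
}

#' Dynamic time warping distance between two series
#'
#' Minimal accumulated squared pointwise difference over all monotone warping
#' paths with steps (1,0), (0,1), (1,1), anchored at both ends; the square
#' root of the accumulated cost is returned, so for equal-length series the
#' DTWD is bounded above by the Euclidean distance (the diagonal path is one
#' admissible alignment).
#'
#' @param a,b Numeric vectors (typically 25-value fingerprints); need not be
#'   of equal length.
#' @param cfg A [dtw_config()].
#' @return A single non-negative number.
#' @examples
#' dtwd(c(0, 0, 1), c(0, 1, 1)) # 0: warping absorbs the shift
#' @export
dtwd <- function(a, b, cfg = dtw_config()) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("dtwd: empty input series")
  if (anyNA(a) || anyNA(b) || !all(is.finite(a)) || !all(is.finite(b))) {
    stop("dtwd: inputs must be finite and free of NA/NaN")
  }
  dtw_dist_cpp(a, b, window_int(cfg))
}

#' DTW kernel similarity
#'
#' `exp(-gamma * DTWD(a, b))`, a similarity in (0, 1] with value 1 iff the
#' DTW distance is zero. Note the kernel is not guaranteed positive
#' semidefinite; the classifier tolerates indefinite kernel matrices.
#'
#' @inheritParams dtwd
#' @return A similarity in (0, 1].
#' @export
dtw_kernel <- function(a, b, cfg = dtw_config()) {
  exp(-cfg$gamma * dtwd(a, b, cfg))
}

#' Pairwise DTW distance matrix
#'
#' Computes all pairwise DTW distances between two collections of series.
#' When `B` is omitted the matrix is the symmetric self-distance matrix of
#' `A` with a zero diagonal. The result does not depend on evaluation order.
#'
#' @param A,B Lists of numeric vectors, or numeric matrices with one series
#'   per row. `B` defaults to `A`.
#' @param cfg A [dtw_config()].
#' @return A `length(A)` x `length(B)` numeric matrix.
#' @export
pairwise_dtwd <- function(A, B = NULL, cfg = dtw_config()) {
  A <- as_series_list(A)
  symmetric <- is.null(B)
  B <- if (symmetric) A else as_series_list(B)
  if (length(A) == 0 || length(B) == 0) stop("pairwise_dtwd: empty input")
  ok <- vapply(c(A, B), function(s) length(s) > 0 && all(is.finite(s)), logical(1))
  if (!all(ok)) {
    stop("pairwise_dtwd: non-finite or empty series at position(s) ",
         paste(which(!ok), collapse = ", "))
  }
  pairwise_dtw_cpp(A, B, window_int(cfg), symmetric)
}

#' DTW kernel matrix
#'
#' Elementwise `exp(-gamma * D)` of the pairwise DTW distance matrix; on a
#' single collection the result is symmetric with unit diagonal.
#'
#' @inheritParams pairwise_dtwd
#' @return A numeric matrix of similarities in (0, 1].
#' @export
dtw_kernel_matrix <- function(A, B = NULL, cfg = dtw_config()) {
  exp(-cfg$gamma * pairwise_dtwd(A, B, cfg))
}

window_int <- function(cfg) {
  if (is.null(cfg$window)) -1L else as.integer(cfg$window)
}

as_series_list <- function(x) {
  if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
  } else if (is.list(x)) {
    lapply(x, as.numeric)
  } else {
    list(as.numeric(x))
  }
}
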