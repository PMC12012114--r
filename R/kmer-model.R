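#' Construct a k-mer current-level model
#'
#' A k-mer model maps every k-mer over {A,C,G,T} to the mean ionic current
#' level expected while that k-mer occupies the pore. Models drive both
#' design-time signal prediction and the squiggle simulator.
#'
#' @param tbl A data frame with columns `kmer` and `level_mean`
#'   (optionally `level_sd`).
#' @return A tibble of class `kmer_model` with attribute `k`.
#' @export
kmer_model <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("kmer", "level_mean") %in% names(tbl)))
  kmers <- as.character(tbl$kmer)
  if (anyDuplicated(kmers)) stop("kmer_model: duplicated k-mers")
  k <- nchar(kmers[1])
  bad <- which(nchar(kmers) != k)
  if (length(bad) > 0) {
    stop("kmer_model: inconsistent k-mer length at row(s) ",
         paste(head(bad, 5), collapse = ", "), " (expected k = ", k, ")")
  }
  if (!all(grepl("^[ACGT]+$", kmers))) {
    stop("kmer_model: k-mers must be over the alphabet {A,C,G,T}")
  }
  lv <- as.numeric(tbl$level_mean)
  if (!all(is.finite(lv))) stop("kmer_model: non-finite level_mean")
  out <- tibble::tibble(kmer = kmers, level_mean = lv)
  if ("level_sd" %in% names(tbl)) out$level_sd <- as.numeric(tbl$level_sd)
  structure(out, k = k, class = c("kmer_model", class(out)))
}

#' @export
print.kmer_model <- function(x, ...) {
  cat("<kmer_model> k =", attr(x, "k"), "with", nrow(x), "k-mers\n")
  NextMethod()
}

#' Bundled synthetic k-mer model
#'
#' A pseudo-random 5-mer model with levels uniform in `range` current units,
#' generated deterministically from `seed`. It has the level-table shape of
#' pore k-mer models but carries no pore chemistry; it exists so that design
#' and simulation never require a download.
#'
#' @param k K-mer length (default 5).
#' @param seed Integer seed (default 42, the bundled default).
#' @param range Level range in current units.
#' @return A [kmer_model()] with `4^k` entries.
#' @export
synthetic_kmer_model <- function(k = 5, seed = 42, range = c(60, 130)) {
  stopifnot(k >= 1, k <= 8)
  kmers <- all_kmers(k)
  lv <- withr_seed(seed, runif(length(kmers), range[1], range[2]))
  kmer_model(tibble::tibble(kmer = kmers, level_mean = lv))
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), k),
                                 list(stringsAsFactors = FALSE)))
  # column 1 varies fastest in expand.grid; build strings first-char-major
  apply(as.matrix(grid[, rev(seq_len(k)), drop = FALSE]), 1, paste0,
        collapse = "")
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a k-mer model TSV
#'
#' Parses the tab-separated `kmer` / `level_mean` (/ `level_sd`) table format
#' used by pore-model distributions.
#'
#' @param path Path to a TSV file with a header line.
#' @return A [kmer_model()].
#' @export
load_kmer_model <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("kmer", "level_mean") %in% names(tbl))) {
    stop("load_kmer_model: file must have columns 'kmer' and 'level_mean': ",
         path)
  }
  if (any(!is.finite(suppressWarnings(as.numeric(tbl$level_mean))))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tbl$level_mean))))
    stop("load_kmer_model: non-numeric level_mean at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  kmer_model(tbl)
}

#' Write a k-mer model TSV
#'
#' @param model A [kmer_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_model <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Predict the expected level sequence of a DNA string
#'
#' Slides the k-mer window along `seq` and looks up the model level at each
#' position. The caller supplies the string already oriented in translocation
#' (3' to 5') order; the model is applied as-is.
#'
#' @param seq A DNA string over {A,C,G,T} with `nchar(seq) >= k`.
#' @param model A [kmer_model()].
#' @return A numeric vector of `nchar(seq) - k + 1` levels.
#' @export
predict_levels <- function(seq, model) {
  k <- attr(model, "k")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) stop("predict_levels: sequence shorter than k = ", k)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  lv <- setNames(model$level_mean, model$kmer)[kmers]
  if (anyNA(lv)) {
    missing <- unique(kmers[is.na(lv)])
    stop("predict_levels: k-mer(s) absent from model: ",
         paste(head(missing, 5), collapse = ", "))
  }
  unname(lv)
}

#' Direction-robust k-mers
#'
#' DNA k-mer models describe 5' to 3' sequencing, but the RTA adapter is read
#' 3' to 5'; no model exists for that direction. As a workaround, barcode
#' design restricts itself to k-mers whose level changes little when the
#' k-mer string is reversed, so the standard model remains approximately
#' valid in both reading directions.
#'
#' @param model A [kmer_model()].
#' @param tol Maximum allowed `|level(K) - level(reverse(K))|` in current
#'   units. Default: half the inter-quartile range of the model levels.
#' @return A character vector of retained k-mers (always includes every
#'   k-mer that is its own reversal).
#' @export
bidirectional_kmers <- function(model, tol = NULL) {
  if (is.null(tol)) tol <- 0.5 * stats::IQR(model$level_mean)
  stopifnot(tol >= 0)
  lv <- setNames(model$level_mean, model$kmer)
  rev_k <- vapply(strsplit(model$kmer, ""), function(ch) {
    paste0(rev(ch), collapse = "")
  }, character(1))
  keep <- abs(lv - lv[rev_k]) <= tol
  model$kmer[keep]
}
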