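#' Generate wave-like target signal patterns
#'
#' Builds a family of square/sine hybrid waveforms over a grid of
#' frequencies (1-4 cycles), phases and amplitude signs, normalizes each by
#' median/MAD, and greedily selects `n_targets` of them maximizing the
#' minimum pairwise DTW distance (farthest-pair start, then maximin
#' additions). Mutually distant wave-like patterns make the downstream
#' barcode classes separable in signal space.
#'
#' @param n_targets Number of target patterns (>= 2; default 12).
#' @param length Pattern length in segments (default 25, the fingerprint
#'   length).
#' @param seed Integer seed (the construction is deterministic; the seed
#'   only fixes tie-breaks).
#' @return A tibble with columns `pattern_id` and `values` (list column of
#'   normalized level vectors).
#' @export
make_targets <- function(n_targets = 12, length = 25, seed = 1) {
  stopifnot(n_targets >= 2)
  grid <- expand.grid(freq = 1:4, phase = c(0, 0.5, 1, 1.5) * pi,
                      shape = c("square", "sine"), sign = c(1, -1),
                      stringsAsFactors = FALSE)
  if (nrow(grid) < n_targets) {
    stop("make_targets: waveform grid smaller than n_targets")
  }
  tt <- seq_len(length)
  fam <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    y <- sin(2 * pi * g$freq * (tt - 1) / length + g$phase)
    if (g$shape == "square") y <- sign(y) + 0.15 * y
    y <- g$sign * y
    # median-centered, sd-scaled: the MAD of a near-two-valued square wave
    # is degenerate, so the robust scale uses the sd here
    (y - median(y)) / sd(y)
  })
  dup <- duplicated(vapply(fam, function(v) paste(round(v, 9), collapse = ","),
                           character(1)))
  fam <- fam[!dup]
  if (length(fam) < n_targets) {
    stop("make_targets: waveform grid smaller than n_targets after ",
         "deduplication")
  }
  D <- withr_seed(seed, pairwise_dtwd(fam))
  sel <- maximin_select(D, n_targets)
  tibble::tibble(pattern_id = sprintf("target_%02d", seq_len(n_targets)),
                 values = fam[sel])
}

# greedy maximin subset: start from the globally farthest pair, then add the
# point whose minimum distance to the selected set is largest
maximin_select <- function(D, k) {
  M <- nrow(D)
  stopifnot(k >= 2, k <= M)
  ij <- arrayInd(which.max(D), dim(D))
  sel <- sort(c(ij[1], ij[2]))
  while (length(sel) < k) {
    rest <- setdiff(seq_len(M), sel)
    mind <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

# random sequence of length L whose every k-mer is in `allowed`, built by a
# walk on the (k-1)-overlap graph; NULL if the walk dead-ends repeatedly
random_allowed_seq <- function(allowed, L, k, tries = 50) {
  pref <- substr(allowed, 1, k - 1)
  succ <- split(allowed, pref)
  for (t in seq_len(tries)) {
    s <- sample(allowed, 1)
    while (nchar(s) < L) {
      nxt <- succ[[substr(s, nchar(s) - k + 2, nchar(s))]]
      if (is.null(nxt)) break
      pick <- nxt[sample.int(length(nxt), 1)]
      s <- paste0(s, substr(pick, k, k))
    }
    if (nchar(s) >= L) return(substr(s, 1, L))
  }
  NULL
}

seq_is_allowed <- function(seq, allowed_set, k) {
  n <- nchar(seq)
  all(substring(seq, 1:(n - k + 1), k:n) %in% allowed_set)
}

#' Score barcode candidates against target patterns
#'
#' For each target pattern, stochastic hill-climbing over barcode sequences
#' of length `L` composed only of `allowed_kmers`: starting from random
#' valid sequences, single-base mutations are proposed and accepted when
#' they reduce the DTW distance between the candidate's median/MAD
#' normalized predicted level sequence and the target. All evaluated
#' sequences are pooled and the `top_n` best distinct ones per target are
#' returned, so the pool size is `n_targets * top_n` (duplicates across
#' targets are retained).
#'
#' @param targets Target tibble from [make_targets()].
#' @param model A [kmer_model()].
#' @param allowed_kmers Character vector of permitted k-mers (e.g. from
#'   [bidirectional_kmers()]).
#' @param L Barcode length in bases (default 18).
#' @param top_n Candidates kept per target (default 50).
#' @param search_budget Total mutation proposals per target (default 4000).
#' @param n_starts Random restarts per target (default 20).
#' @param seed Integer seed.
#' @return A tibble (`candidate pool`) with columns `seq`, `source_target`,
#'   `score` (DTWD to its target; lower is better).
#' @export
score_candidates <- function(targets, model, allowed_kmers, L = 18,
                             top_n = 50, search_budget = 4000, n_starts = 20,
                             seed = 1) {
  stopifnot(top_n >= 1, length(allowed_kmers) > 0)
  k <- attr(model, "k")
  bases <- c("A", "C", "G", "T")
  withr_seed(seed, {
    pools <- lapply(seq_len(nrow(targets)), function(ti) {
      target <- targets$values[[ti]]
      seen <- new.env(parent = emptyenv())
      score_of <- function(s) {
        dtwd(normalize_segments(predict_levels(s, model), "median_mad"),
             target)
      }
      note <- function(s, sc) {
        if (is.null(seen[[s]])) assign(s, sc, envir = seen)
      }
      per_start <- max(1, search_budget %/% n_starts)
      for (r in seq_len(n_starts)) {
        cur <- random_allowed_seq(allowed_kmers, L, k)
        if (is.null(cur)) next
        cur_sc <- score_of(cur)
        note(cur, cur_sc)
        for (step in seq_len(per_start)) {
          pos <- sample.int(L, 1)
          base <- sample(bases, 1)
          if (substr(cur, pos, pos) == base) next
          prop <- cur
          substr(prop, pos, pos) <- base
          if (!seq_is_allowed(prop, allowed_kmers, k)) next
          sc <- score_of(prop)
          note(prop, sc)
          if (sc < cur_sc) {
            cur <- prop
            cur_sc <- sc
          }
        }
      }
      seqs <- ls(seen)
      if (length(seqs) < top_n) {
        stop("score_candidates: found only ", length(seqs),
             " distinct valid sequences for ", targets$pattern_id[ti],
             "; increase search_budget or relax allowed_kmers")
      }
      scores <- vapply(seqs, function(s) seen[[s]], numeric(1))
      ord <- order(scores, seqs)[seq_len(top_n)]
      tibble::tibble(seq = seqs[ord], source_target = targets$pattern_id[ti],
                     score = unname(scores[ord]))
    })
    dplyr::bind_rows(pools)
  })
}

mdp_objective <- function(D, sel) {
  sum(D[sel, sel][upper.tri(D[sel, sel])])
}

#' Solve the Maximal Diversity Problem
#'
#' Select `k` of `M` items maximizing the sum of pairwise distances
#' (reported as the upper-triangle sum over the selected set). `greedy`
#' starts from the globally farthest pair and iteratively adds the candidate
#' with the largest summed distance to the current selection; `exchange`
#' refines the greedy solution by 1-swap local search to a local optimum;
#' `exhaustive` enumerates all subsets (gated to `choose(M, k) <= 1e6`
#' instances, as the problem is NP-hard in general).
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param k Subset size, `1 <= k <= M`.
#' @param method `"exchange"` (default), `"greedy"` or `"exhaustive"`.
#' @return A list with `selected` (indices), `delta` (0/1 indicator of
#'   length M) and `objective`.
#' @export
solve_mdp <- function(D, k, method = c("exchange", "greedy", "exhaustive")) {
  method <- match.arg(method)
  M <- nrow(D)
  if (k > M) stop("solve_mdp: k exceeds the pool size")
  stopifnot(k >= 1, isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  as_result <- function(sel) {
    delta <- integer(M)
    delta[sel] <- 1L
    list(selected = sort(sel), delta = delta,
         objective = mdp_objective(D, sel))
  }
  if (k == M) return(as_result(seq_len(M)))
  if (k == 1) return(as_result(1L))
  if (method == "exhaustive") {
    if (choose(M, k) > 1e6) {
      stop("solve_mdp: exhaustive search gated to choose(M, k) <= 1e6")
    }
    combs <- combn(M, k)
    objs <- apply(combs, 2, function(sel) mdp_objective(D, sel))
    return(as_result(combs[, which.max(objs)]))
  }
  ij <- arrayInd(which.max(D), dim(D))
  sel <- sort(c(ij[1], ij[2]))
  while (length(sel) < k) {
    rest <- setdiff(seq_len(M), sel)
    gain <- colSums(D[sel, rest, drop = FALSE])
    sel <- c(sel, rest[which.max(gain)])
  }
  if (method == "exchange") {
    improved <- TRUE
    iter <- 0
    while (improved && iter < 200) {
      improved <- FALSE
      iter <- iter + 1
      for (i in seq_along(sel)) {
        others <- sel[-i]
        base_sum <- colSums(D[others, , drop = FALSE])
        cur_obj <- base_sum[sel[i]]
        rest <- setdiff(seq_len(M), sel)
        best <- which.max(base_sum[rest])
        if (base_sum[rest][best] > cur_obj + 1e-12) {
          sel[i] <- rest[best]
          improved <- TRUE
        }
      }
    }
  }
  as_result(sel)
}

#' Design a maximally separated barcode set
#'
#' End-to-end de novo design: wave-like target patterns, per-target
#' candidate search through the k-mer model, the full pairwise DTW distance
#' matrix over the candidate pool's normalized predicted signals, and
#' Maximal Diversity selection of `k` barcodes. Duplicate sequences are
#' retained in the pool but never appear twice in the final selection.
#'
#' @param model A [kmer_model()].
#' @param k Number of barcodes to select (default 12).
#' @param n_targets Number of target patterns (default 12).
#' @param top_n Candidates per target (default 50).
#' @param L Barcode length (default 18).
#' @param bidir_tol Tolerance forwarded to [bidirectional_kmers()].
#' @param search_budget,n_starts Search effort per target, see
#'   [score_candidates()].
#' @param target_length Target pattern length (default 25).
#' @param mdp_method Passed to [solve_mdp()].
#' @param seed Integer seed.
#' @param dtw_cfg A [dtw_config()].
#' @return An object of class `barcode_design`: list with `barcodes`
#'   (tibble: `barcode_id`, `seq`, `source_target`, `score`), `distances`
#'   (k x k DTWD matrix of the selection), `objective`, `pool`, `pool_distances`,
#'   `targets`.
#' @export
design_barcodes <- function(model = synthetic_kmer_model(), k = 12,
                            n_targets = 12, top_n = 50, L = 18,
                            bidir_tol = NULL, search_budget = 4000,
                            n_starts = 20, target_length = 25,
                            mdp_method = "exchange", seed = 1,
                            dtw_cfg = dtw_config()) {
  allowed <- bidirectional_kmers(model, bidir_tol)
  targets <- make_targets(n_targets, target_length, seed)
  pool <- score_candidates(targets, model, allowed, L = L, top_n = top_n,
                           search_budget = search_budget, n_starts = n_starts,
                           seed = seed + 1)
  sigs <- lapply(pool$seq, function(s) {
    normalize_segments(predict_levels(s, model), "median_mad")
  })
  D <- pairwise_dtwd(sigs, cfg = dtw_cfg)
  # duplicate sequences have zero mutual distance; forbid co-selection by
  # solving on distinct sequences, then map back to pool rows
  first_idx <- match(unique(pool$seq), pool$seq)
  sol <- solve_mdp(D[first_idx, first_idx, drop = FALSE], k,
                   method = mdp_method)
  sel <- first_idx[sol$selected]
  barcodes <- tibble::tibble(barcode_id = sprintf("BC%02d", seq_len(k)),
                             seq = pool$seq[sel],
                             source_target = pool$source_target[sel],
                             score = pool$score[sel])
  structure(list(barcodes = barcodes,
                 distances = D[sel, sel, drop = FALSE],
                 objective = sol$objective,
                 pool = pool,
                 pool_distances = D,
                 targets = targets,
                 seed = seed),
            class = "barcode_design")
}

#' @export
print.barcode_design <- function(x, ...) {
  cat("<barcode_design>", nrow(x$barcodes), "barcodes from a pool of",
      nrow(x$pool), "candidates\n")
  cat("  MDP objective:", format(x$objective, digits = 6),
      " min pairwise DTWD:",
      format(min(x$distances[upper.tri(x$distances)]), digits = 4), "\n")
  print(x$barcodes, ...)
  invisible(x)
}

#' @export
tidy.barcode_design <- function(x, ...) x$barcodes

#' @export
glance.barcode_design <- function(x, ...) {
  ut <- x$distances[upper.tri(x$distances)]
  tibble::tibble(n_barcodes = nrow(x$barcodes), pool_size = nrow(x$pool),
                 objective = x$objective, min_pairwise_dtwd = min(ut),
                 mean_pairwise_dtwd = mean(ut))
}

#' @export
autoplot.barcode_design <- function(object, ...) {
  tgt <- tidyr::unnest(
    tibble::tibble(pattern_id = object$targets$pattern_id,
                   value = object$targets$values) |>
      dplyr::mutate(segment = purrr::map(.data$value, seq_along)),
    cols = c("value", "segment"))
  ggplot2::ggplot(tgt, ggplot2::aes(.data$segment, .data$value)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::facet_wrap(~pattern_id) +
    ggplot2::labs(x = "Segment", y = "Normalized level",
                  title = "Design target patterns")
}

#' Log10 size of the barcode design space
#'
#' Number of ways to choose `k` barcodes from all `4^L` sequences of length
#' `L`, computed on the log scale via `lchoose` (the count itself vastly
#' exceeds double precision range for realistic `L`).
#'
#' @param L Barcode length (default 18).
#' @param k Set size (default 12).
#' @return `log10(choose(4^L, k))`.
#' @examples
#' 10^(design_space_log10(18, 12) - 121) # about 2.3 (x 10^121 sets)
#' @export
design_space_log10 <- function(L = 18, k = 12) {
  lchoose(4^L, k) / log(10)
}
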