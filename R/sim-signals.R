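#' Squiggle simulator configuration
#'
#' Parameters of the synthetic direct RNA sequencing read generator. A
#' simulated read reproduces the three-part anatomy of a dRNA-seq squiggle:
#' the DNA adapter signal (ending in the barcode), a long near-constant
#' poly(A) plateau, and an RNA-body random walk. Within each part, every base
#' (pore event) emits its expected current level for a stochastic dwell time,
#' and Gaussian measurement noise is added on top.
#'
#' @param sample_rate Sampling rate in Hz (default 3012, RNA002-like).
#' @param translocation_speed Motor speed in nt/s (default 70), so the mean
#'   dwell is `sample_rate / translocation_speed` samples per base.
#' @param dwell_dispersion Dispersion of the negative-binomial dwell
#'   distribution (variance = mu + dispersion * mu^2). 0 gives deterministic
#'   dwells of `round(mu)` samples.
#' @param noise_sd Additive Gaussian noise sd in current units.
#' @param polyA_level Poly(A) plateau level in current units.
#' @param polyA_len_nt Poly(A) tail length in nucleotides.
#' @param adapter_seq_len Total adapter length in bases, leader + barcode.
#'   The true RTA base count is not publicly documented; 50 nt is a free
#'   choice that yields a plausible adapter span.
#' @param barcode_len Barcode length in bases (default 18, the customizable
#'   stretch of the RTA adapter).
#' @param rna_body_len_nt RNA body length in nucleotides.
#' @param body_step_sd Per-base step sd of the RNA-body level random walk.
#' @param seed Default integer seed for dataset generation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 3012,
                       translocation_speed = 70,
                       dwell_dispersion = 0.3,
                       noise_sd = 2.5,
                       polyA_level = 108,
                       polyA_len_nt = 60,
                       adapter_seq_len = 50,
                       barcode_len = 18,
                       rna_body_len_nt = 60,
                       body_step_sd = 6,
                       seed = 1L) {
  cfg <- list(sample_rate = sample_rate,
              translocation_speed = translocation_speed,
              dwell_dispersion = dwell_dispersion,
              noise_sd = noise_sd,
              polyA_level = polyA_level,
              polyA_len_nt = as.integer(polyA_len_nt),
              adapter_seq_len = as.integer(adapter_seq_len),
              barcode_len = as.integer(barcode_len),
              rna_body_len_nt = as.integer(rna_body_len_nt),
              body_step_sd = body_step_sd,
              seed = as.integer(seed))
  if (cfg$sample_rate / cfg$translocation_speed <= 1) {
    stop("sim_config: mean dwell must exceed one sample per base")
  }
  if (cfg$dwell_dispersion < 0 || cfg$noise_sd < 0) {
    stop("sim_config: dispersion and noise_sd must be >= 0")
  }
  if (cfg$polyA_len_nt <= 0 || cfg$adapter_seq_len <= 0) {
    stop("sim_config: lengths must be strictly positive")
  }
  if (cfg$barcode_len >= cfg$adapter_seq_len) {
    stop("sim_config: barcode_len must be smaller than adapter_seq_len")
  }
  structure(cfg, class = "sim_config")
}

#' RNA004-like simulator preset
#'
#' Same generator with the faster chemistry's sampling rate and motor speed.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_rna004 <- function(...) {
  sim_config(sample_rate = 4000, translocation_speed = 130, ...)
}

# Fixed adapter leader shared by all barcode classes: only the final
# barcode_len bases differ between classes. Deterministic regardless of the
# caller's RNG state.
adapter_leader <- function(cfg) {
  n <- cfg$adapter_seq_len - cfg$barcode_len
  bases <- withr_seed(191919L, sample(c("A", "C", "G", "T"), n, replace = TRUE))
  paste0(bases, collapse = "")
}

draw_dwells <- function(n, cfg) {
  mu <- cfg$sample_rate / cfg$translocation_speed
  if (cfg$dwell_dispersion == 0) {
    rep(as.integer(round(mu)), n)
  } else {
    pmax(1L, rnbinom(n, mu = mu, size = 1 / cfg$dwell_dispersion))
  }
}

#' Simulate one direct RNA squiggle read
#'
#' Expands the predicted per-base level sequence of the adapter (leader +
#' barcode, in 3' to 5' translocation order), the poly(A) plateau and an
#' RNA-body random walk into a raw current trace with per-base dwell times
#' and additive Gaussian noise. Exact event boundaries are recorded as truth
#' metadata: `adapter_end` is the number of adapter samples (the poly(A)
#' onset), `polya_end` the sample index at which the plateau ends.
#'
#' @param barcode_seq DNA barcode string (3' to 5'), alphabet {A,C,G,T}.
#' @param model A [kmer_model()] covering all adapter k-mers.
#' @param cfg A [sim_config()].
#' @param read_id Read identifier.
#' @param seed Optional integer; when given, the read is generated under a
#'   local RNG state so repeated calls are bit-identical.
#' @return A one-row tibble with columns `read_id`, `signal` (list),
#'   `sample_rate`, `label`, `adapter_end`, `polya_end`, and truth list
#'   columns `levels` and `dwells`.
#' @export
simulate_read <- function(barcode_seq, model, cfg = sim_config(),
                          read_id = "read_1", seed = NULL) {
  if (!grepl("^[ACGT]+$", barcode_seq)) {
    stop("simulate_read: barcode_seq must be over {A,C,G,T}")
  }
  if (nchar(barcode_seq) != cfg$barcode_len) {
    stop("simulate_read: barcode_seq must have length ", cfg$barcode_len)
  }
  gen <- function() simulate_read_impl(barcode_seq, model, cfg, read_id)
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

simulate_read_impl <- function(barcode_seq, model, cfg, read_id,
                               label = barcode_seq) {
  adapter_seq <- paste0(adapter_leader(cfg), barcode_seq)
  lv_adapter <- predict_levels(adapter_seq, model)
  lv_polyA <- rep(cfg$polyA_level, cfg$polyA_len_nt)
  lv_body <- if (cfg$rna_body_len_nt > 0) {
    steps <- rnorm(cfg$rna_body_len_nt, 0, cfg$body_step_sd)
    pmin(130, pmax(60, cfg$polyA_level - 10 + cumsum(steps)))
  } else numeric(0)
  levels <- c(lv_adapter, lv_polyA, lv_body)
  dwells <- draw_dwells(length(levels), cfg)
  n_ad <- length(lv_adapter)
  n_pa <- length(lv_polyA)
  signal <- rep(levels, dwells)
  if (cfg$noise_sd > 0) signal <- signal + rnorm(length(signal), 0, cfg$noise_sd)
  tibble::tibble(
    read_id = read_id,
    signal = list(signal),
    sample_rate = cfg$sample_rate,
    label = label,
    adapter_end = sum(dwells[seq_len(n_ad)]),
    polya_end = sum(dwells[seq_len(n_ad + n_pa)]),
    levels = list(levels),
    dwells = list(as.integer(dwells))
  )
}

# Corruption operators producing noise-class reads: inserted stall plateau,
# adapter truncation (>= 50% removed), poly(A) deletion.
corrupt_read <- function(read, type) {
  sig <- read$signal[[1]]
  a_end <- read$adapter_end
  p_end <- read$polya_end
  if (type == "stall") {
    # stalled adapter: the pore stalls at a poly(A)-like level before the
    # barcode finishes translocating, so the barcode tail of the adapter is
    # replaced by a long plateau and the apparent DNA/RNA boundary is early
    keep <- as.integer(runif(1, 0.18, 0.45) * a_end)
    len <- as.integer(runif(1, 4500, 8000))
    lvl <- runif(1, 96, 124)
    stall <- lvl + rnorm(len, 0, 1.5)
    sig <- c(sig[seq_len(keep)], stall, sig[(a_end + 1):length(sig)])
    p_end <- p_end - (a_end - keep) + len
    a_end <- keep
  } else if (type == "truncate") {
    # adapter truncation: at least half the adapter is lost, but enough
    # remains for the read to pass boundary detection as a (bad) adapter
    cut <- min(as.integer(a_end * runif(1, 0.6, 0.88)), a_end - 400L)
    cut <- max(cut, 1L)
    sig <- sig[-seq_len(cut)]
    a_end <- a_end - cut
    p_end <- p_end - cut
  } else if (type == "no_polya") {
    sig <- sig[-((a_end + 1):p_end)]
    p_end <- a_end
  } else {
    stop("corrupt_read: unknown corruption type ", type)
  }
  read$signal <- list(sig)
  read$label <- "NOISE"
  read$adapter_end <- a_end
  read$polya_end <- p_end
  read
}

#' Simulate a labeled dataset of squiggle reads
#'
#' Generates `n_per_barcode` reads per barcode plus a share of corrupted
#' reads labeled `"NOISE"`. Noise reads mimic common signal irregularities,
#' drawn with equal probability: a stalled adapter whose barcode tail is
#' replaced by a poly(A)-like plateau (premature DNA/RNA boundary), a
#' truncated adapter (at least half removed), or a deleted poly(A) tail. `noise_fraction` is
#' the fraction of the *total* output that is noise, i.e.
#' `n_noise = round(noise_fraction / (1 - noise_fraction) * k * n_per_barcode)`.
#'
#' @param barcode_set Character vector of barcode sequences (3' to 5').
#' @param n_per_barcode Reads per barcode (>= 1).
#' @param noise_fraction Proportion of the output labeled NOISE, in [0, 1).
#' @param cfg A [sim_config()].
#' @param model A [kmer_model()]; default the bundled synthetic model.
#' @param seed Integer seed; default `cfg$seed`.
#' @return A tibble of reads (one row per read) in shuffled order, with a
#'   `replicate_id` column splitting the data into three pseudo-replicates
#'   and a `source` column recording the barcode each read (including each
#'   corrupted read) was generated from.
#' @export
simulate_dataset <- function(barcode_set, n_per_barcode, noise_fraction = 0,
                             cfg = sim_config(),
                             model = synthetic_kmer_model(),
                             seed = cfg$seed) {
  if (length(barcode_set) == 0) stop("simulate_dataset: empty barcode set")
  stopifnot(n_per_barcode >= 1, noise_fraction >= 0, noise_fraction < 1)
  withr_seed(seed, {
    barcode_set <- unname(barcode_set)
    n_bc <- length(barcode_set) * n_per_barcode
    n_noise <- round(noise_fraction / (1 - noise_fraction) * n_bc)
    labels <- rep(barcode_set, each = n_per_barcode)
    reads <- vector("list", n_bc + n_noise)
    for (i in seq_len(n_bc)) {
      reads[[i]] <- simulate_read_impl(labels[i], model, cfg,
                                       sprintf("read_%05d", i))
    }
    if (n_noise > 0) {
      noise_src <- sample(barcode_set, n_noise, replace = TRUE)
      ops <- sample(c("stall", "truncate", "no_polya"), n_noise, replace = TRUE)
      for (j in seq_len(n_noise)) {
        base <- simulate_read_impl(noise_src[j], model, cfg,
                                   sprintf("read_%05d", n_bc + j))
        reads[[n_bc + j]] <- corrupt_read(base, ops[j])
      }
    }
    out <- dplyr::bind_rows(reads)
    out$source <- c(labels, if (n_noise > 0) noise_src)
    out <- out[sample(nrow(out)), ]
    out$replicate_id <- sprintf("rep%d", (seq_len(nrow(out)) %% 3L) + 1L)
    out
  })
}

#' Plot a simulated or imported read
#'
#' Squiggle trace with the adapter/poly(A) boundaries overlaid when present.
#'
#' @param read A one-row read tibble (see [simulate_read()]).
#' @return A ggplot object.
#' @export
plot_read <- function(read) {
  stopifnot(nrow(read) == 1)
  df <- tibble::tibble(sample = seq_along(read$signal[[1]]),
                       current = read$signal[[1]])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$current)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::labs(x = "Sample", y = "Current (a.u.)",
                  title = read$read_id, subtitle = read$label)
  if (!is.null(read$adapter_end) && is.finite(read$adapter_end)) {
    p <- p + ggplot2::geom_vline(xintercept = c(read$adapter_end,
                                                read$polya_end),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
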