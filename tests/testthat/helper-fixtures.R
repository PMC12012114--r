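# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, builder(), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

fx_kmer_model <- function() fixture("kmer_model", function() {
  synthetic_kmer_model()
})

# four fixed barcodes used by the small-scale tests
fx_barcodes4 <- function() {
  c(BC1 = "ACGTACGTACGTACGTAC", BC2 = "TTTTGGGGCCCCAAAATT",
    BC3 = "GACTGACTGACTGACTGA", BC4 = "CATGCATGCATGCATGCA")
}

# small labeled dataset: 4 barcodes x 30 reads + 10% noise
fx_dataset_small <- function() fixture("dataset_small", function() {
  simulate_dataset(fx_barcodes4(), 30, noise_fraction = 0.1,
                   cfg = sim_config(), model = fx_kmer_model(), seed = 42)
})

fx_fps_small <- function() fixture("fps_small", function() {
  extract_fingerprints(fx_dataset_small())
})

# a small trained model on clean fingerprints of the small dataset
fx_model_small <- function() fixture("model_small", function() {
  fps <- fx_fps_small()
  ok <- fps[fps$ok & fps$label != "NOISE", ]
  train_demux(ok, seed = 7)
})

# synthetic "fingerprints" drawn around class template patterns; cheap
# stand-in for simulated reads when only the classifier/training logic is
# under test
fx_gaussian_fps <- function(n_per_class = 30, n_classes = 3, len = 25,
                            noise = 0.3, seed = 1) {
  set.seed(seed)
  templates <- lapply(seq_len(n_classes), function(c) {
    sin(2 * pi * c * seq_len(len) / len + c)
  })
  rows <- list()
  for (c in seq_len(n_classes)) {
    for (i in seq_len(n_per_class)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = sprintf("g%02d_%03d", c, i),
        fingerprint = list(templates[[c]] + rnorm(len, 0, noise)),
        ok = TRUE, qc_flags = "", label = sprintf("class%d", c))
    }
  }
  dplyr::bind_rows(rows)
}

# independent DTW oracle: exhaustive enumeration of all monotone
# boundary-anchored warping paths (steps (1,0), (0,1), (1,1))
dtw_oracle <- function(a, b) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  rec <- function(i, j, cost) {
    cost <- cost + (a[i] - b[j])^2
    if (cost >= best) return(invisible())
    if (i == n && j == m) {
      best <<- cost
      return(invisible())
    }
    if (i < n) rec(i + 1, j, cost)
    if (j < m) rec(i, j + 1, cost)
    if (i < n && j < m) rec(i + 1, j + 1, cost)
  }
  rec(1, 1, 0)
  sqrt(best)
}

# independent MDP brute force over all k-subsets
mdp_bruteforce <- function(D, k) {
  combs <- combn(nrow(D), k)
  objs <- apply(combs, 2, function(s) sum(D[s, s][upper.tri(D[s, s])]))
  list(selected = sort(combs[, which.max(objs)]), objective = max(objs))
}
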