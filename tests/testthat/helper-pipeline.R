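# The full study pipeline at its reference scale, shared by the
# whole-pipeline tests. Built once per test run and memoised.
#
# Conditions: 12 de-novo designed barcodes (reduced search budget), a
# training pool of 450 reads per barcode with an 18% share of corrupted
# reads for noise-class mining, the 80 + 80 + 240 diversity-stratified
# training set plus 400 noise instances, and a clean test set of 200 reads
# per barcode evaluated at confidence cutoff 0.5.
acceptance_pipeline <- function(base_seed = 100) {
  fixture(sprintf("pipeline_%d", base_seed), function() {
    km <- synthetic_kmer_model()
    cfg <- sim_config()
    design <- design_barcodes(km, k = 12, n_targets = 12, top_n = 50,
                              L = 18, search_budget = 1500, n_starts = 15,
                              seed = base_seed + 1)
    bcs <- design$barcodes$seq
    train_ds <- simulate_dataset(bcs, 450, noise_fraction = 0.18, cfg, km,
                                 seed = base_seed + 2)
    train_fps <- extract_fingerprints(train_ds)
    pool <- train_fps[train_fps$ok, ]
    pool$label <- train_ds$source[match(pool$read_id, train_ds$read_id)]
    train_set <- build_training_set(pool, n_noise = 400,
                                    seed = base_seed + 3)
    model <- train_demux(train_set, seed = base_seed + 4)
    test_ds <- simulate_dataset(bcs, 200, noise_fraction = 0, cfg, km,
                                seed = base_seed + 5)
    test_fps <- extract_fingerprints(test_ds)
    pred <- predict(model, test_fps, conf_cutoff = 0.5)
    list(km = km, cfg = cfg, design = design, train_ds = train_ds,
         train_fps = train_fps, train_set = train_set, model = model,
         test_ds = test_ds, test_fps = test_fps, pred = pred,
         eval = evaluate_demux(pred))
  })
}
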