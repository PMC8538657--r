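# Shared phantom builders and memoised heavy fixtures.

# Scaled acquisition used throughout the tests: the full 74-frame / 2.3 s /
# 8-baseline dynamic protocol on a reduced 96x96x8 grid, so one subject
# stays ~40 MB and the whole suite runs on one CPU.
seg_phantom_config <- function(seed, noise_sigma = 0, ...) {
  phantom_config(dim = c(96L, 96L, 8L), spacing = c(2.2, 2.2, 3.0),
                 semi_axes = c(11, 18, 3), noise_sigma = noise_sigma,
                 seed = seed, ...)
}

# Smaller grid for classification / PK tests.
small_phantom_config <- function(seed, ...) {
  phantom_config(dim = c(64L, 64L, 6L), spacing = c(2.2, 2.2, 3.0),
                 semi_axes = c(6, 9, 2), seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, compute) {
  if (!exists(key, .fixture_cache)) assign(key, compute(), .fixture_cache)
  get(key, .fixture_cache)
}

# One end-to-end pipeline run on noiseless scaled phantoms with the reduced
# U-Net (depth 2, base filters 16, 10 epochs, ~200 patches over 3 training
# subjects). Trains once per session; both the segmentation and the GFR
# acceptance checks read from this report.
acceptance_pipeline_report <- function() {
  memo("pipeline_report", function() {
    subjects <- lapply(1:4, function(i) seg_phantom_config(seed = i))
    names(subjects) <- paste0("s", 1:4)
    cfg <- pipeline_config(
      subjects, test_subject = "s4",
      unet = list(depth = 2, base_filters = 16, dropout = 0.2),
      train = train_config(epochs = 10, batch_size = 8, seed = 1),
      classifier = classifier_config("svm_rbf"),
      n_offsets = 2L, seed = 1L)
    run_pipeline(cfg)
  })
}

# Labelled PCA features of noisy partial-volume phantoms for the
# classification benchmark (2 training subjects, 1 held out).
classification_fixture <- function() {
  memo("classification", function() {
    phs <- lapply(1:3, function(i)
      make_phantom(small_phantom_config(seed = 10 + i, noise_sigma = 0.03,
                                        pv_width = 0.15)))
    sets <- lapply(1:2, function(i) {
      ph <- phs[[i]]
      extract_time_courses(ph$series,
                           ph$kidney_masks$left | ph$kidney_masks$right,
                           ph$labels, subject = paste0("s", i))
    })
    pooled <- renodce:::bind_time_courses(sets)
    pca <- fit_pca(pooled, k = 20)
    feats <- transform_pca(pca, pooled)
    ph <- phs[[3]]
    tcs <- extract_time_courses(ph$series,
                                ph$kidney_masks$left | ph$kidney_masks$right,
                                ph$labels, subject = "s3")
    list(pooled = pooled, pca = pca, feats = feats,
         test_tcs = tcs, test_feats = transform_pca(pca, tcs))
  })
}
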