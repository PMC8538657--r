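test_that("time-course extraction is one row per in-mask voxel", {
  ph <- make_phantom(small_phantom_config(seed = 1, noise_sigma = 0))
  km <- ph$kidney_masks$left | ph$kidney_masks$right
  tcs <- extract_time_courses(ph$series, km, ph$labels, normalize = FALSE)
  expect_equal(nrow(tcs$courses), sum(km))
  expect_equal(nrow(tcs$coords), sum(km))
  # noiseless cortex rows equal the forward-model signal curve
  curve <- ph$curves$signal[ph$curves$compartment == "cortex"]
  rows <- tcs$courses[tcs$labels == 1L, , drop = FALSE]
  expect_lt(max(abs(sweep(rows, 2, curve))), 1e-12)
  # identical voxels give identical rows
  expect_equal(rows[1, ], rows[nrow(rows), ])
  expect_error(extract_time_courses(ph$series, array(FALSE, dim(km))),
               "empty")
})

test_that("PCA model contracts: rank, variance, orthonormality", {
  set.seed(1)
  # exact mixtures of two basis curves: rank-2 data
  t <- seq(0, 1, length.out = 40)
  b1 <- sin(2 * pi * t); b2 <- t^2
  w <- matrix(runif(200), 100, 2)
  x <- w %*% rbind(b1, b2)
  tcs <- structure(list(courses = x, times = t, subject = "s1"),
                   class = "time_course_set")
  m <- fit_pca(tcs, k = 2)
  expect_equal(sum(m$explained[1:2]), 1.0, tolerance = 1e-9)
  expect_equal(m$components %*% t(m$components), diag(2), tolerance = 1e-9)
  # explained ratios are non-increasing
  expect_true(all(diff(m$explained_all) < 1e-12))
  expect_error(fit_pca(tcs, k = 50), "frames")
})

test_that("retained components explain at least the requested variance", {
  fx <- classification_fixture()
  m <- fx$pca
  expect_gte(sum(m$explained), 0.90)
  expect_gte(m$k, 20)
})

test_that("PCA projection matches brute-force dot products", {
  fx <- classification_fixture()
  m <- fx$pca
  x <- fx$pooled$courses[1:5, , drop = FALSE]
  got <- transform_pca(m, x)
  for (i in 1:5) for (j in 1:3) {
    expect_equal(got[i, j],
                 sum((x[i, ] - m$mean) * m$components[j, ]),
                 tolerance = 1e-10)
  }
  # the mean curve projects to the origin
  expect_lt(max(abs(transform_pca(m, matrix(m$mean, 1)))), 1e-9)
  # a pure component maps to a one-hot feature (up to scale)
  pure <- matrix(m$mean + 2 * m$components[1, ], 1)
  f <- transform_pca(m, pure)
  expect_equal(as.numeric(f), c(2, rep(0, ncol(f) - 1)), tolerance = 1e-9)
})

test_that("PCA reconstruction error decreases with more components", {
  fx <- classification_fixture()
  x <- fx$pooled$courses[1:200, ]
  errs <- vapply(c(2, 5, 10, 20), function(k) {
    cm <- fx$pca$components[1:k, , drop = FALSE]
    f <- sweep(x, 2, fx$pca$mean) %*% t(cm)
    rec <- f %*% cm + matrix(fx$pca$mean, nrow(x), ncol(x), byrow = TRUE)
    sqrt(mean((rec - x)^2))
  }, 1.0)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("time-resampling adapter handles variable-length inputs", {
  fx <- classification_fixture()
  tcs <- fx$test_tcs
  # re-sample the held-out courses to a 60-frame grid and transform back
  t2 <- seq(min(tcs$times), max(tcs$times), length.out = 60)
  courses2 <- t(apply(tcs$courses, 1, function(r)
    approx(tcs$times, r, xout = t2)$y))
  tcs2 <- structure(list(courses = courses2, times = t2,
                         subject = tcs$subject),
                    class = "time_course_set")
  f1 <- transform_pca(fx$pca, tcs)
  f2 <- transform_pca(fx$pca, tcs2)
  expect_equal(dim(f2), dim(f1))
  expect_lt(median(abs(f2 - f1)), 0.05 * median(abs(f1)) + 0.02)
  expect_error(transform_pca(fx$pca, courses2), "frame count")
})

test_that("class balancing matches the pelvis class size", {
  set.seed(1)
  labels <- c(rep(1L, 580), rep(2L, 310), rep(3L, 110))
  feats <- matrix(rnorm(1000 * 3), 1000, 3)
  bal <- balance_classes(feats, labels, seed = 2)
  expect_equal(as.numeric(table(bal$labels)), c(110, 110, 110))
  # already balanced input is a permutation of itself
  lab2 <- rep(1:3, each = 50)
  f2 <- matrix(seq_len(150), 150, 1)
  b2 <- balance_classes(f2, lab2, seed = 3)
  expect_setequal(as.numeric(b2$features), seq_len(150))
  # undersampling is without replacement
  b1 <- balance_classes(feats, labels, seed = 2)
  expect_identical(bal$features, b1$features)
  expect_error(balance_classes(feats[1:890, ], labels[1:890]), "class")
})

test_that("all three classifiers separate linearly separable blobs", {
  set.seed(4)
  n <- 60
  feats <- rbind(matrix(rnorm(n * 2, 0), n, 2),
                 matrix(rnorm(n * 2, 6), n, 2),
                 matrix(rnorm(n * 2, -6), n, 2))
  labels <- rep(1:3, each = n)
  for (alg in c("svm_rbf", "logistic", "xgboost")) {
    clf <- train_classifier(feats, labels, classifier_config(alg))
    pred <- predict(clf, feats)
    expect_equal(classification_report(labels, pred)$balanced_accuracy, 1.0)
  }
  # logistic probabilities are a softmax: rows sum to one
  clf <- train_classifier(feats, labels, classifier_config("logistic"))
  pr <- predict(clf, feats[1:7, ], type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 7), tolerance = 1e-9)
  expect_error(train_classifier(feats[1:10, ], rep(1L, 10)), "single class")
})

test_that("SVM grid search picks the generalising hyperparameters", {
  set.seed(5)
  n <- 40
  feats <- rbind(matrix(rnorm(n * 2, 0, 1.5), n, 2),
                 matrix(rnorm(n * 2, 4, 1.5), n, 2))
  labels <- rep(1:2, each = n)
  # single-point grid returns that point
  g1 <- grid_search_svm(feats, labels, gamma_grid = 0.05, cost_grid = 1)
  expect_equal(c(g1$gamma, g1$cost), c(0.05, 1))
  # a tiny RBF width memorises the training folds and fails on held-out
  # folds; the search must prefer the moderate width
  g2 <- grid_search_svm(feats, labels, gamma_grid = c(0.05, 50),
                        cost_grid = 1, seed = 6)
  expect_equal(g2$gamma, 0.05)
  # seeded fold assignment makes the search reproducible
  g3 <- grid_search_svm(feats, labels, gamma_grid = c(0.05, 50),
                        cost_grid = 1, seed = 6)
  expect_identical(g2$results, g3$results)
  expect_error(grid_search_svm(feats[1:3, ], labels[1:3], 0.05, 1), "folds")
})

test_that("voxel classification maps the whole mask and respects provenance", {
  phs <- lapply(1:3, function(i)
    make_phantom(small_phantom_config(seed = 20 + i, noise_sigma = 0)))
  sets <- lapply(1:2, function(i) {
    ph <- phs[[i]]
    extract_time_courses(ph$series,
                         ph$kidney_masks$left | ph$kidney_masks$right,
                         ph$labels, subject = paste0("s", i))
  })
  pooled <- renodce:::bind_time_courses(sets)
  pca <- fit_pca(pooled, k = 20)
  feats <- transform_pca(pca, pooled)
  bal <- balance_classes(feats, pooled$labels, seed = 1)
  clf <- train_classifier(bal$features, bal$labels,
                          classifier_config("svm_rbf"),
                          train_subjects = c("s1", "s2"))
  ph <- phs[[3]]
  km <- ph$kidney_masks$left | ph$kidney_masks$right
  lab <- classify_voxels(clf, pca, ph$series, km)
  # output support equals the mask, all in-mask voxels labelled 1..3
  expect_equal(lab > 0, km)
  expect_true(all(lab[km] %in% 1:3))
  # noiseless pure-compartment voxels are recovered perfectly
  rep <- classification_report(ph$labels[km], lab[km])
  expect_equal(rep$balanced_accuracy, 1.0)
  # empty mask gives an all-zero map
  empty <- classify_voxels(clf, pca, ph$series, array(FALSE, dim(km)))
  expect_equal(sum(empty), 0)
  # provenance mismatch is an error
  pca2 <- pca; pca2$train_subjects <- c("s1", "s9")
  expect_error(classify_voxels(clf, pca2, ph$series, km), "cohort")
})

test_that("DWT features preserve energy and match a per-level oracle", {
  expect_equal(dwt_features(matrix(0, 2, 64)), matrix(0, 2, 64))
  set.seed(6)
  x <- matrix(rnorm(3 * 64), 3, 64)
  d <- dwt_features(x)
  # Parseval for the orthonormal periodised transform
  expect_equal(rowSums(d^2), rowSums(x^2), tolerance = 1e-6)
  # one-level oracle: periodic convolution + downsampling by 2
  lo <- renodce:::DB4_LO
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  s <- x[1, ]
  n <- length(s)
  a1 <- vapply(seq(1, n, by = 2), function(i)
    sum(s[(i + seq_along(lo) - 2) %% n + 1] * lo), 1.0)
  d1 <- vapply(seq(1, n, by = 2), function(i)
    sum(s[(i + seq_along(lo) - 2) %% n + 1] * hi), 1.0)
  one <- dwt_features(matrix(s, 1), levels = 1)
  expect_equal(as.numeric(one), c(a1, d1), tolerance = 1e-10)
  expect_error(dwt_features(x, wavelet = "haar"), "unknown wavelet")
  expect_error(dwt_features(matrix(0, 1, 4)), "shorter")
})

test_that("k-means partitions separated blobs and is seeded", {
  set.seed(7)
  n <- 50
  feats <- rbind(matrix(rnorm(n * 2, 0, 0.3), n, 2),
                 matrix(rnorm(n * 2, 5, 0.3), n, 2),
                 matrix(rnorm(n * 2, -5, 0.3), n, 2))
  truth <- rep(1:3, each = n)
  km <- kmeans_partition(feats, 3, seed = 1, truth = truth)
  expect_equal(classification_report(truth, km$mapped)$balanced_accuracy, 1)
  km2 <- kmeans_partition(feats, 3, seed = 1)
  expect_identical(km$cluster, km2$cluster)
  # within-cluster SSE no worse than a random assignment
  sse <- function(assign) {
    sum(vapply(unique(assign), function(k) {
      cl <- feats[assign == k, , drop = FALSE]
      sum(scale(cl, scale = FALSE)^2)
    }, 1.0))
  }
  set.seed(8)
  expect_lt(km$kmeans$tot.withinss, sse(sample(1:3, 3 * n, TRUE)))
  expect_error(kmeans_partition(feats[1:2, ], 3), "fewer samples")
})

test_that("20 PCA aggregates lose at most one point against raw courses", {
  fx <- classification_fixture()
  bal <- balance_classes(fx$feats[, 1:20], fx$pooled$labels, seed = 1)
  clf_pca <- train_classifier(bal$features, bal$labels,
                              classifier_config("svm_rbf"))
  ba_pca <- classification_report(
    fx$test_tcs$labels,
    predict(clf_pca, fx$test_feats[, 1:20]))$balanced_accuracy
  balr <- balance_classes(fx$pooled$courses, fx$pooled$labels, seed = 1)
  clf_raw <- train_classifier(balr$features, balr$labels,
                              classifier_config("svm_rbf"))
  ba_raw <- classification_report(
    fx$test_tcs$labels,
    predict(clf_raw, fx$test_tcs$courses))$balanced_accuracy
  expect_gte(ba_pca, ba_raw - 0.01)
})
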