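# Stage 2: voxel-wise classification of signal time-courses into cortex,
# medulla and pelvis. PCA feature aggregates + SVM (primary), multinomial
# logistic regression or XGBoost; DWT and k-means baselines for comparison.

#' Extract in-mask voxel time-courses
#'
#' One row per in-mask voxel; optionally normalised by the per-voxel
#' baseline mean (S(t) / mean of pre-contrast frames) to remove coil-gain
#' scale, which makes cross-subject transfer well-posed.
#'
#' @param series a `dynamic_series`.
#' @param mask logical 3D array on the series grid.
#' @param labels optional compartment label map; attaches labels 1/2/3.
#' @param normalize divide each voxel's course by its baseline mean.
#' @param subject,session provenance fields.
#' @return object of class `time_course_set`: `courses` (n x n_frames
#'   matrix), `coords` (tibble x/y/z), `labels` (or NULL), `times`,
#'   provenance fields.
#' @export
extract_time_courses <- function(series, mask, labels = NULL,
                                 normalize = TRUE,
                                 subject = "s1", session = 1L) {
  d <- dim(series$data)
  stopifnot(all(dim(mask) == d[1:3]))
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  m <- matrix(series$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  if (normalize) {
    b <- rowMeans(m[, seq_len(series$n_baseline), drop = FALSE])
    b[b <= 0] <- 1
    m <- m / b
  }
  co <- arrayInd(idx, d[1:3])
  structure(list(
    courses = m,
    coords = tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3]),
    labels = if (!is.null(labels)) as.integer(labels[idx]) else NULL,
    times = series$frame_times,
    normalized = normalize,
    subject = subject, session = session),
    class = "time_course_set")
}

#' @export
print.time_course_set <- function(x, ...) {
  cat("<time_course_set>", nrow(x$courses), "voxels x",
      ncol(x$courses), "frames",
      if (!is.null(x$labels)) "(labelled)" else "", "\n")
  invisible(x)
}

#' Fit a PCA feature extractor on training time-courses
#'
#' Principal component analysis of the (centred) time-courses. `k`
#' components are retained, raised if necessary until the cumulative
#' explained variance reaches `min_variance`. Must be fitted on
#' training-cohort voxels only; the training subjects are recorded for the
#' leakage audit.
#'
#' @param train a `time_course_set` (or several bound rows of courses).
#' @param k minimum number of feature aggregates (default 20).
#' @param min_variance cumulative explained-variance requirement.
#' @return object of class `pca_model`: `mean`, `components`
#'   (k x n_frames, orthonormal rows), `explained` variance ratios,
#'   `k`, `times`, `train_subjects`.
#' @export
fit_pca <- function(train, k = 20L, min_variance = 0.90) {
  x <- train$courses
  if (k > ncol(x)) stop("k exceeds the number of frames", call. = FALSE)
  if (nrow(x) <= k) stop("need more voxels than components", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  kk <- as.integer(k)
  cum <- cumsum(ratios)
  while (kk < length(ratios) && cum[kk] < min_variance) kk <- kk + 1L
  structure(list(mean = unname(pc$center),
                 components = unname(t(pc$rotation[, seq_len(kk),
                                                   drop = FALSE])),
                 explained = ratios[seq_len(kk)],
                 explained_all = ratios,
                 k = kk,
                 times = train$times,
                 train_subjects = unique(train$subject)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", x$k, "components;",
      round(100 * sum(x$explained), 1), "% variance explained\n")
  invisible(x)
}

#' Project time-courses onto fitted PCA components
#'
#' Centred projection. Courses sampled on a different time grid are first
#' linearly resampled onto the training grid, so the transform acts as an
#' adapter for variable-length inputs.
#'
#' @param model a `pca_model`.
#' @param tcs a `time_course_set`, or a plain matrix on the training grid.
#' @param resample allow linear time-resampling when the frame count
#'   differs from the training grid.
#' @return n x k feature matrix.
#' @export
transform_pca <- function(model, tcs, resample = TRUE) {
  x <- if (inherits(tcs, "time_course_set")) tcs$courses else tcs
  if (ncol(x) != length(model$mean)) {
    if (!resample || !inherits(tcs, "time_course_set"))
      stop("frame count does not match the PCA model", call. = FALSE)
    x <- t(apply(x, 1, function(r)
      stats::approx(tcs$times, r, xout = model$times, rule = 2)$y))
  }
  sweep(x, 2, model$mean) %*% t(model$components)
}

#' Balance training classes to the pelvis class size
#'
#' The cortex and medulla subsets are resampled to match the size of the
#' pelvis category (random undersampling without replacement; a class
#' smaller than the pelvis is oversampled with replacement). Seeded.
#'
#' @param features n x k feature matrix.
#' @param labels integer labels 1/2/3 (3 = pelvis).
#' @param seed integer seed.
#' @return list with resampled `features` and `labels`.
#' @export
balance_classes <- function(features, labels, seed = 1L) {
  stopifnot(nrow(features) == length(labels))
  cls <- 1:3
  if (!all(cls %in% labels))
    stop("all three classes must be present", call. = FALSE)
  set.seed(seed)
  target <- sum(labels == 3L)
  keep <- unlist(lapply(cls, function(k) {
    idx <- which(labels == k)
    if (length(idx) == target) idx
    else if (length(idx) > target) sample(idx, target)
    else sample(idx, target, replace = TRUE)
  }))
  list(features = features[keep, , drop = FALSE], labels = labels[keep])
}

#' Classifier configuration
#'
#' Hyperparameters for the three supported algorithms: SVM with RBF kernel
#' (gamma = 0.05, C = 1, one-vs-one multiclass), L2-regularised multinomial
#' logistic regression, and XGBoost (10 trees, depth 4, gamma = 0.1,
#' lambda = 0.9, softmax objective).
#'
#' @param algorithm `"svm_rbf"`, `"logistic"` or `"xgboost"`.
#' @param svm_gamma,svm_cost RBF kernel width and soft-margin cost.
#' @param logistic_decay L2 weight-decay of the multinomial logistic fit.
#' @param xgb_trees,xgb_depth,xgb_gamma,xgb_lambda XGBoost ensemble size,
#'   max tree depth, split penalty and L2 leaf regularisation.
#' @param seed integer seed.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(algorithm = c("svm_rbf", "logistic", "xgboost"),
                              svm_gamma = 0.05, svm_cost = 1,
                              logistic_decay = 1e-4,
                              xgb_trees = 10L, xgb_depth = 4L,
                              xgb_gamma = 0.1, xgb_lambda = 0.9,
                              seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(svm_gamma > 0, svm_cost > 0, logistic_decay >= 0,
            xgb_trees >= 1, xgb_depth >= 1, xgb_gamma >= 0, xgb_lambda >= 0)
  structure(list(algorithm = algorithm, svm_gamma = svm_gamma,
                 svm_cost = svm_cost, logistic_decay = logistic_decay,
                 xgb_trees = as.integer(xgb_trees),
                 xgb_depth = as.integer(xgb_depth),
                 xgb_gamma = xgb_gamma, xgb_lambda = xgb_lambda,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train a compartment classifier on feature vectors
#'
#' @param features n x k feature matrix (typically PCA aggregates).
#' @param labels integer labels 1/2/3.
#' @param config a [classifier_config()].
#' @param train_subjects provenance: subjects whose voxels were used.
#' @return object of class `voxel_classifier` exposing [predict()] with
#'   class labels and, for logistic/xgboost, per-class probabilities.
#' @export
train_classifier <- function(features, labels,
                             config = classifier_config(),
                             train_subjects = NULL) {
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2)
    stop("training data contain a single class", call. = FALSE)
  set.seed(config$seed)
  fit <- switch(
    config$algorithm,
    svm_rbf = e1071::svm(x = features, y = factor(labels, levels = 1:3),
                         kernel = "radial", gamma = config$svm_gamma,
                         cost = config$svm_cost, scale = FALSE),
    logistic = nnet::multinom(y ~ ., data = data.frame(
      y = factor(labels, levels = 1:3), features),
      decay = config$logistic_decay, maxit = 300, trace = FALSE),
    xgboost = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = 3,
                    max_depth = config$xgb_depth, gamma = config$xgb_gamma,
                    lambda = config$xgb_lambda, nthread = 1,
                    seed = config$seed),
      data = xgboost::xgb.DMatrix(as.matrix(features),
                                  label = labels - 1L),
      nrounds = config$xgb_trees))
  structure(list(fit = fit, config = config,
                 train_subjects = train_subjects,
                 n_features = ncol(features)),
            class = "voxel_classifier")
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat("<voxel_classifier>", x$config$algorithm, "on", x$n_features,
      "features; trained on",
      if (is.null(x$train_subjects)) "unspecified cohort" else
        paste(x$train_subjects, collapse = ", "), "\n")
  invisible(x)
}

#' Predict compartment labels for feature vectors
#'
#' @param object a `voxel_classifier`.
#' @param newdata n x k feature matrix.
#' @param type `"class"` for integer labels 1/2/3, `"prob"` for per-class
#'   probabilities where the algorithm provides them.
#' @param ... unused.
#' @return integer labels or probability matrix.
#' @export
predict.voxel_classifier <- function(object, newdata,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$n_features)
    stop("feature count mismatch", call. = FALSE)
  cfg <- object$config
  if (cfg$algorithm == "svm_rbf") {
    if (type == "prob")
      stop("SVM votes are hard; probabilities not provided", call. = FALSE)
    return(as.integer(as.character(predict(object$fit, newdata))))
  }
  if (cfg$algorithm == "logistic") {
    pr <- predict(object$fit, data.frame(newdata), type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    if (type == "prob") return(pr)
    return(max.col(pr))
  }
  pr <- predict(object$fit, xgboost::xgb.DMatrix(as.matrix(newdata)))
  if (!is.matrix(pr)) pr <- matrix(pr, ncol = 3, byrow = TRUE)
  if (type == "prob") return(pr)
  max.col(pr)
}

#' Grid search of SVM hyperparameters by cross-validation
#'
#' Exhaustive search over (gamma, C) maximising mean balanced accuracy in
#' seeded k-fold cross-validation; ties broken toward smaller C, then
#' smaller gamma (the simpler model).
#'
#' @param features n x k feature matrix.
#' @param labels integer labels.
#' @param gamma_grid,cost_grid candidate values.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @return list with `gamma`, `cost` and the full `results` tibble.
#' @export
grid_search_svm <- function(features, labels, gamma_grid = c(0.01, 0.05, 0.5),
                            cost_grid = c(0.1, 1, 10), folds = 5L,
                            seed = 1L) {
  stopifnot(length(gamma_grid) > 0, length(cost_grid) > 0)
  n <- nrow(features)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  res <- purrr::pmap_dfr(grid, function(gamma, cost) {
    ba <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      m <- e1071::svm(x = features[tr, , drop = FALSE],
                      y = factor(labels[tr]),
                      kernel = "radial", gamma = gamma, cost = cost,
                      scale = FALSE)
      pred <- as.integer(as.character(predict(
        m, features[!tr, , drop = FALSE])))
      classification_report(labels[!tr], pred)$balanced_accuracy
    }, 1.0)
    tibble::tibble(gamma = gamma, cost = cost,
                   balanced_accuracy = mean(ba, na.rm = TRUE))
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$balanced_accuracy),
                        .data$cost, .data$gamma)
  list(gamma = res$gamma[1], cost = res$cost[1], results = res)
}

#' Classify every in-mask voxel into a renal compartment
#'
#' Extracts the voxel time-courses, projects them through the fitted PCA
#' model and assigns each voxel to cortex, medulla or pelvis. The PCA model
#' and the classifier must come from the same training cohort; a
#' provenance mismatch is an error.
#'
#' @param model a `voxel_classifier`.
#' @param pca the `pca_model` fitted on the same training cohort.
#' @param series a `dynamic_series`.
#' @param mask logical 3D kidney mask.
#' @return integer compartment label map (0 outside the mask).
#' @export
classify_voxels <- function(model, pca, series, mask) {
  if (!is.null(model$train_subjects) && !is.null(pca$train_subjects) &&
      !setequal(model$train_subjects, pca$train_subjects))
    stop("classifier and PCA come from different training cohorts",
         call. = FALSE)
  out <- array(0L, dim = dim(series$data)[1:3])
  if (!any(mask)) return(out)
  tcs <- extract_time_courses(series, mask)
  feats <- transform_pca(pca, tcs)
  out[which(mask)] <- predict(model, feats)
  out
}

# Daubechies-4 (8-tap) orthonormal decomposition filter.
DB4_LO <- c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

#' Multilevel discrete wavelet transform features
#'
#' Baseline feature set for comparison with PCA: each time-course is
#' decomposed with the Daubechies-4 (8-tap) filter bank using periodised
#' boundary handling (the transform stays orthogonal, so signal energy is
#' preserved), and the approximation plus all detail coefficients are
#' concatenated.
#'
#' @param tcs a `time_course_set` or numeric matrix (rows = voxels).
#' @param wavelet only `"db4"` is provided.
#' @param levels decomposition depth; default is the maximum number of
#'   full levels for the signal length.
#' @return n x m coefficient matrix.
#' @export
dwt_features <- function(tcs, wavelet = "db4", levels = NULL) {
  if (!identical(wavelet, "db4"))
    stop("unknown wavelet '", wavelet, "'", call. = FALSE)
  x <- if (inherits(tcs, "time_course_set")) tcs$courses else tcs
  n <- ncol(x)
  lo <- DB4_LO
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  if (n < length(lo))
    stop("signal shorter than the wavelet filter", call. = FALSE)
  if (is.null(levels)) levels <- max(1L, floor(log2(n / (length(lo) - 1))))
  step <- function(s) {
    m <- length(s)
    if (m %% 2 == 1) { s <- c(s, s[1]); m <- m + 1 }  # periodised odd pad
    idx <- outer(seq(1, m, by = 2), seq_along(lo) - 1, "+")
    idx <- (idx - 1) %% m + 1
    sm <- matrix(s[idx], nrow = m / 2)
    list(a = as.numeric(sm %*% lo), d = as.numeric(sm %*% hi))
  }
  decompose <- function(s) {
    det <- list()
    for (l in seq_len(levels)) {
      r <- step(s)
      det[[l]] <- r$d
      s <- r$a
    }
    c(s, rev(det) |> unlist())
  }
  t(apply(x, 1, decompose))
}

#' k-means partition of feature vectors (clustering baseline)
#'
#' Clusters the voxels' feature vectors with k-means (seeded). For
#' evaluation only, clusters can be mapped to compartment classes by
#' majority ground-truth vote; no deployment-time labeling heuristic is
#' provided, since unsupervised cluster naming requires one.
#'
#' @param features n x k feature matrix.
#' @param k number of clusters (default 3).
#' @param seed integer seed for initialisation.
#' @param truth optional ground-truth labels for the majority-vote mapping.
#' @return list with `cluster` (raw k-means labels), `mapped` (class
#'   labels via majority vote, when `truth` given), `map`, and the
#'   `kmeans` fit.
#' @export
kmeans_partition <- function(features, k = 3L, seed = 1L, truth = NULL) {
  if (nrow(features) < k) stop("fewer samples than clusters", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = 5, iter.max = 50)
  mapped <- NULL; map <- NULL
  if (!is.null(truth)) {
    map <- vapply(seq_len(k), function(cl) {
      tt <- truth[km$cluster == cl]
      if (length(tt) == 0) return(NA_integer_)
      as.integer(names(which.max(table(tt))))
    }, 1L)
    mapped <- map[km$cluster]
  }
  list(cluster = km$cluster, mapped = mapped, map = map, kmeans = km)
}
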