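# End-to-end orchestration: simulate -> coarse segmentation -> largest
# component -> fine segmentation -> mean cortex curve -> 2CFM fit -> GFR ->
# evaluation; plus the leave-one-subject-out driver.

# Pool several labelled time-course sets into one (for cohort-level fits).
bind_time_courses <- function(sets) {
  structure(list(
    courses = do.call(rbind, lapply(sets, `[[`, "courses")),
    coords = dplyr::bind_rows(lapply(sets, `[[`, "coords")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    times = sets[[1]]$times,
    normalized = sets[[1]]$normalized,
    subject = unlist(lapply(sets, function(s)
      rep(s$subject[1], nrow(s$courses)))),
    session = sets[[1]]$session),
    class = "time_course_set")
}

#' Pipeline configuration
#'
#' Assembles the per-stage settings consumed by [run_pipeline()] and
#' [loso_driver()].
#'
#' @param subjects named list of [phantom_config()] objects, one per
#'   simulated subject.
#' @param test_subject name of the held-out subject.
#' @param unet list of [build_unet()] arguments.
#' @param train a [train_config()].
#' @param classifier a [classifier_config()].
#' @param pca list with `k` and `min_variance`.
#' @param n_frames_seg enhancement frames used for patch extraction.
#' @param n_offsets vertical augmentation offsets per slice and side.
#' @param seed global seed.
#' @param out_dir optional output directory; when set, stage artifacts are
#'   written there and re-used on rerun if the configuration is unchanged.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects, test_subject = names(subjects)[1],
                            unet = list(depth = 2, base_filters = 16,
                                        dropout = 0.2),
                            train = train_config(epochs = 10),
                            classifier = classifier_config(),
                            pca = list(k = 20, min_variance = 0.90),
                            n_frames_seg = 3L, n_offsets = 10L,
                            seed = 1L, out_dir = NULL) {
  stopifnot(length(subjects) >= 2, test_subject %in% names(subjects))
  structure(list(subjects = subjects, test_subject = test_subject,
                 unet = unet, train = train, classifier = classifier,
                 pca = pca, n_frames_seg = as.integer(n_frames_seg),
                 n_offsets = as.integer(n_offsets),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Run `compute()` or load a cached stage artifact keyed by config hash.
stage_cached <- function(name, hash, dir, compute) {
  if (is.null(dir)) return(compute())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".rds"))
  meta <- file.path(dir, paste0(name, ".hash"))
  if (file.exists(path) && file.exists(meta) &&
      identical(readLines(meta, warn = FALSE)[1], hash)) {
    message("stage '", name, "': reusing cached artifact")
    return(readRDS(path))
  }
  res <- compute()
  saveRDS(res, path)
  writeLines(hash, meta)
  res
}

pipeline_fail <- function(stage, e, hint) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       "\n  hint: ", hint, call. = FALSE)
}

#' Run the full segmentation and quantification pipeline on phantoms
#'
#' Simulates all configured subjects, trains the U-Net and the
#' PCA + classifier stack on the training subjects only, applies them to
#' the held-out subject, fits the 2CFM to the mean cortical concentration
#' curve per kidney and reports SK-GFR against the phantom ground truth,
#' together with segmentation and classification metrics and a manifest of
#' written artifacts. No held-out data influence any fitted component
#' (audited via provenance).
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `gfr` (per-side tibble with
#'   estimate, truth and percent error), `fits` (per-side `pk_fit`),
#'   `coarse` (IoU of the refined whole-kidney mask), `fine`
#'   (`segmentation_score`), `classifier_report`, `masks`, `labels`,
#'   `manifest`, `models`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  dir <- config$out_dir
  test <- config$test_subject
  train_subj <- setdiff(names(config$subjects), test)

  phantoms <- stage_cached("simulate", hash, dir, function() {
    lapply(config$subjects, make_phantom)
  })

  net <- stage_cached("unet", hash, dir, function() {
    sets <- list()
    for (s in train_subj) {
      ph <- phantoms[[s]]
      frames <- select_enhancement_frames(ph$series, config$n_frames_seg)
      kmask <- ph$kidney_masks$left | ph$kidney_masks$right
      for (f in frames)
        sets[[length(sets) + 1]] <- extract_patches(
          ph$series$data[, , , f], kmask, mode = "train",
          n_offsets = config$n_offsets, seed = config$seed + f,
          subject = s, frame_index = f)
    }
    patches <- bind_patch_sets(sets)
    args <- c(config$unet, list(seed = config$seed))
    tryCatch(train_unet(patches, do.call(build_unet, args), config$train),
             error = function(e) pipeline_fail(
               "train-seg", e, "check patch extraction and U-Net config"))
  })

  models <- stage_cached("classifier", hash, dir, function() {
    sets <- lapply(train_subj, function(s) {
      ph <- phantoms[[s]]
      kmask <- ph$kidney_masks$left | ph$kidney_masks$right
      extract_time_courses(ph$series, kmask, ph$labels, subject = s)
    })
    pooled <- bind_time_courses(sets)
    pca <- fit_pca(pooled, k = config$pca$k,
                   min_variance = config$pca$min_variance)
    feats <- transform_pca(pca, pooled)
    bal <- balance_classes(feats, pooled$labels, seed = config$seed)
    clf <- train_classifier(bal$features, bal$labels, config$classifier,
                            train_subjects = train_subj)
    list(pca = pca, clf = clf)
  })

  # leakage audit: no held-out provenance in any fitted component
  leaked <- c(intersect(net$train_subjects, test),
              intersect(models$pca$train_subjects, test),
              intersect(models$clf$train_subjects, test))
  if (length(leaked) > 0)
    stop("leakage audit failed: held-out subject in training provenance",
         call. = FALSE)

  ph <- phantoms[[test]]
  frames <- select_enhancement_frames(ph$series, config$n_frames_seg)
  mid <- frames[ceiling(length(frames) / 2)]
  masks <- tryCatch(predict_mask(net, ph$series, mid),
                    error = function(e) pipeline_fail(
                      "segment", e, "was the network trained?"))
  masks <- lapply(masks, largest_component)
  union_mask <- masks$left | masks$right
  truth_union <- ph$kidney_masks$left | ph$kidney_masks$right

  labels_pred <- tryCatch(
    classify_voxels(models$clf, models$pca, ph$series, union_mask),
    error = function(e) pipeline_fail(
      "classify", e, "PCA/classifier provenance must match"))

  cfgp <- ph$config
  gfr_rows <- list(); fits <- list()
  for (s in c("left", "right")) {
    cortex_side <- labels_pred == 1L & masks[[s]]
    side_labels <- array(0L, dim = dim(labels_pred))
    side_labels[cortex_side] <- 1L
    sig <- mean_cortex_curve(ph$series, side_labels)
    conc <- signal_to_concentration(sig, ph$series$n_baseline,
                                    cfgp$T10[["cortex"]], cfgp$r1,
                                    ph$series$TR, ph$series$flip_angle)
    fit <- tryCatch(
      fit_2cfm(as.numeric(conc), ph$aif, times = ph$series$frame_times),
      error = function(e) pipeline_fail(
        "fit-pk", e, "is there enhancement in the predicted cortex?"))
    fits[[s]] <- fit
    g <- compute_gfr(fit$params[["ktrans"]], side_labels, cfgp$spacing)
    truth_row <- ph$truth[ph$truth$side == s, ]
    gfr_rows[[s]] <- tibble::tibble(
      side = s,
      gfr_est = g$gfr_ml_min,
      gfr_true = truth_row$sk_gfr_ml_min,
      cortex_volume_est = g$cortex_volume_ml,
      cortex_volume_true = truth_row$cortex_volume_ml,
      ktrans_est = fit$params[["ktrans"]],
      pct_error = 100 * (g$gfr_ml_min - truth_row$sk_gfr_ml_min) /
        truth_row$sk_gfr_ml_min)
  }

  fine <- multiclass_scores(labels_pred, ph$labels)
  tcs_truth <- extract_time_courses(ph$series, truth_union, ph$labels,
                                    subject = test)
  clf_report <- classification_report(
    tcs_truth$labels,
    predict(models$clf, transform_pca(models$pca, tcs_truth)))

  manifest <- tibble::tibble(stage = character(), artifact = character(),
                             md5 = character())
  if (!is.null(dir)) {
    paths <- list(
      c("segment", "mask_left.nii.gz"), c("segment", "mask_right.nii.gz"),
      c("classify", "labels_pred.nii.gz"))
    write_labels(array(as.integer(masks$left), dim(masks$left)),
                 file.path(dir, "mask_left.nii.gz"), cfgp$spacing)
    write_labels(array(as.integer(masks$right), dim(masks$right)),
                 file.path(dir, "mask_right.nii.gz"), cfgp$spacing)
    write_labels(labels_pred, file.path(dir, "labels_pred.nii.gz"),
                 cfgp$spacing)
    report <- list(seed = config$seed, config_hash = hash,
                   gfr = dplyr::bind_rows(gfr_rows))
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    files <- vapply(paths, `[`, character(1), 2)
    files <- c(files, "report.json")
    manifest <- tibble::tibble(
      stage = c(vapply(paths, `[`, character(1), 1), "report"),
      artifact = files,
      md5 = unname(tools::md5sum(file.path(dir, files))))
  }

  structure(list(gfr = dplyr::bind_rows(gfr_rows), fits = fits,
                 coarse = list(
                   whole_iou = iou(union_mask, truth_union),
                   left_iou = iou(masks$left, ph$kidney_masks$left),
                   right_iou = iou(masks$right, ph$kidney_masks$right)),
                 fine = fine, classifier_report = clf_report,
                 masks = masks, labels = labels_pred,
                 manifest = manifest,
                 models = list(unet = net, pca = models$pca,
                               clf = models$clf),
                 seed = config$seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> whole-kidney IoU:", round(x$coarse$whole_iou, 3),
      "| weighted compartment IoU:", round(x$fine$weighted_iou, 3), "\n")
  print(x$gfr)
  invisible(x)
}

#' Leave-one-subject-out cross-validation driver
#'
#' For every subject, trains the segmentation network, the PCA transform
#' and the classifier on the remaining subjects only, evaluates on the
#' held-out subject, and aggregates the per-subject metrics into means and
#' standard deviations.
#'
#' @param config a [pipeline_config()]; its `test_subject` field is
#'   ignored and each subject is held out in turn.
#' @return list of class `loso_report`: `per_subject` tibble, `aggregate`
#'   tibble (mean and SD per metric), `reports` (per-subject
#'   `pipeline_report`s).
#' @export
loso_driver <- function(config) {
  stopifnot(inherits(config, "pipeline_config"),
            length(config$subjects) >= 2)
  subjects <- names(config$subjects)
  reports <- list()
  rows <- list()
  for (s in subjects) {
    cfg <- config
    cfg$test_subject <- s
    if (!is.null(cfg$out_dir))
      cfg$out_dir <- file.path(cfg$out_dir, paste0("holdout_", s))
    rep <- run_pipeline(cfg)
    reports[[s]] <- rep
    rows[[s]] <- tibble::tibble(
      subject = s,
      whole_iou = rep$coarse$whole_iou,
      weighted_iou = rep$fine$weighted_iou,
      balanced_accuracy = rep$classifier_report$balanced_accuracy,
      gfr_pct_error = mean(abs(rep$gfr$pct_error)))
  }
  per_subject <- dplyr::bind_rows(rows)
  metrics <- setdiff(names(per_subject), "subject")
  aggregate <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_subject[[m]]), 1.0),
    sd = vapply(metrics, function(m) stats::sd(per_subject[[m]]), 1.0))
  structure(list(per_subject = per_subject, aggregate = aggregate,
                 reports = reports),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat("<loso_report>", nrow(x$per_subject), "held-out subjects\n")
  print(x$aggregate)
  invisible(x)
}
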