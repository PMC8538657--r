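# Stage 1: whole-kidney semantic segmentation. Enhancement-frame selection,
# 96x96 single-kidney patch extraction with augmentation, U-Net training
# and prediction, largest-connected-component refinement.

PATCH <- 96L   # patch side; halves of a 192-wide in-plane matrix
PLANE <- 192L  # working in-plane size; inputs are centre-cropped/padded

#' Select perfusion-phase enhancement frames
#'
#' Picks the frame of maximum signal enhancement plus its immediate
#' neighbours. Enhancement is measured label-free as the 99th percentile of
#' (frame - baseline mean) within the central image band (central half in
#' both in-plane directions): a high quantile that lands inside the
#' strongly enhancing cortex without requiring annotations at inference
#' time.
#'
#' @param series a `dynamic_series`.
#' @param n number of frames to return (default 3: the peak frame, one
#'   preceding, one succeeding).
#' @return integer frame indices (1-based), strictly after the baseline.
#' @export
select_enhancement_frames <- function(series, n = 3L) {
  d <- dim(series$data)
  nb <- series$n_baseline
  post <- (nb + 1L):d[4]
  if (n > length(post))
    stop("n exceeds available post-baseline frames", call. = FALSE)
  bx <- seq(floor(d[1] / 4) + 1, ceiling(3 * d[1] / 4))
  by <- seq(floor(d[2] / 4) + 1, ceiling(3 * d[2] / 4))
  base <- apply(series$data[bx, by, , seq_len(nb), drop = FALSE], 1:3, mean)
  enh <- vapply(post, function(t)
    stats::quantile(series$data[bx, by, , t] - base, 0.99, names = FALSE),
    1.0)
  if (max(enh) <= 0.01 * mean(base))
    stop("no enhancement detected", call. = FALSE)
  # the perfusion phase is the FIRST sustained peak of the enhancement
  # curve: cortical uptake peaks during the first pass, before the slow
  # excretory accumulation in the pelvis can dominate the high quantile
  k <- NA_integer_
  np <- length(enh)
  for (i in seq_len(max(np - 2, 0))) {
    if (enh[i] >= 0.3 * max(enh) && enh[i] > enh[i + 1] &&
        enh[i] > enh[i + 2]) { k <- post[i]; break }
  }
  if (is.na(k)) k <- post[which.max(enh)]
  lo <- k - floor((n - 1) / 2)
  hi <- k + ceiling((n - 1) / 2)
  if (lo < post[1]) { hi <- hi + (post[1] - lo); lo <- post[1] }
  if (hi > d[4]) { lo <- lo - (hi - d[4]); hi <- d[4] }
  as.integer(lo:hi)
}

# Centre-crop/pad a 2D slice to PLANE x PLANE.
fit_plane <- function(sl) {
  out <- matrix(0, PLANE, PLANE)
  d <- dim(sl)
  sx <- min(d[1], PLANE); sy <- min(d[2], PLANE)
  ox <- (PLANE - sx) %/% 2; oy <- (PLANE - sy) %/% 2
  ix <- (d[1] - sx) %/% 2; iy <- (d[2] - sy) %/% 2
  out[ox + seq_len(sx), oy + seq_len(sy)] <-
    sl[ix + seq_len(sx), iy + seq_len(sy)]
  out
}

norm01 <- function(p) {
  r <- range(p)
  if (r[2] > r[1]) (p - r[1]) / (r[2] - r[1]) else p * 0
}

#' Extract 96x96 single-kidney image patches
#'
#' The (cropped/padded) 192-wide plane is split into image-left and
#' image-right halves of 96-pixel width. In training mode, up to
#' `n_offsets` vertical patch positions are sampled per slice and side
#' among the positions that retain at least `min_kidney_frac` of that
#' slice-side's kidney pixels, and each patch is mirrored horizontally with
#' probability 1/2; slices without kidney pixels are skipped. In inference
#' mode exactly one vertically centred patch per side per slice is
#' produced. Patches are min-max normalised to \[0, 1\]. Full provenance
#' (subject, session, side, slice, frame, offset, mirrored) is recorded.
#'
#' @param volume 3D array (x, y, z): one frame of a dynamic series.
#' @param mask logical 3D kidney mask (both kidneys), training mode only.
#' @param mode `"train"` or `"infer"`.
#' @param n_offsets vertical positions sampled per slice and side.
#' @param mirror randomly mirror training patches horizontally.
#' @param min_kidney_frac minimum fraction of the slice-side's kidney
#'   pixels a training patch must retain.
#' @param seed integer seed for offset sampling and mirroring.
#' @param subject,session,frame_index provenance fields.
#' @return object of class `patch_set`: `patches` (96 x 96 x n), `masks`
#'   (96 x 96 x n logical, training mode), `provenance` tibble.
#' @export
extract_patches <- function(volume, mask = NULL,
                            mode = c("train", "infer"),
                            n_offsets = 10L, mirror = TRUE,
                            min_kidney_frac = 0.2, seed = 1L,
                            subject = "s1", session = 1L,
                            frame_index = NA_integer_) {
  mode <- match.arg(mode)
  d <- dim(volume)
  stopifnot(length(d) == 3)
  if (mode == "train" && is.null(mask))
    stop("training mode requires a kidney mask", call. = FALSE)
  set.seed(seed)
  sides <- list(image_left = seq_len(PATCH),
                image_right = PATCH + seq_len(PATCH))
  patches <- list(); masks <- list(); prov <- list()
  centre <- (PLANE - PATCH) %/% 2 + 1L
  for (z in seq_len(d[3])) {
    sl <- fit_plane(volume[, , z])
    msl <- if (!is.null(mask)) fit_plane(mask[, , z] * 1) > 0.5 else NULL
    for (s in names(sides)) {
      cols <- sides[[s]]
      if (mode == "infer") {
        p <- norm01(sl[cols, centre + 0:(PATCH - 1)])
        patches[[length(patches) + 1]] <- p
        prov[[length(prov) + 1]] <- tibble::tibble(
          subject = subject, session = session, side = s, slice = z,
          frame = frame_index, offset = centre, mirrored = FALSE)
        next
      }
      kp <- sum(msl[cols, ])
      if (kp == 0) next
      offs <- 1:(PLANE - PATCH + 1)
      keep_frac <- vapply(offs, function(o)
        sum(msl[cols, o + 0:(PATCH - 1)]) / kp, 1.0)
      ok <- offs[keep_frac >= min_kidney_frac]
      if (length(ok) == 0) next
      chosen <- if (length(ok) > n_offsets)
        sort(sample(ok, n_offsets)) else ok
      for (o in chosen) {
        p <- norm01(sl[cols, o + 0:(PATCH - 1)])
        m <- msl[cols, o + 0:(PATCH - 1)]
        flip <- mirror && stats::runif(1) < 0.5
        if (flip) { p <- p[PATCH:1, ]; m <- m[PATCH:1, ] }
        patches[[length(patches) + 1]] <- p
        masks[[length(masks) + 1]] <- m
        prov[[length(prov) + 1]] <- tibble::tibble(
          subject = subject, session = session, side = s, slice = z,
          frame = frame_index, offset = o, mirrored = flip)
      }
    }
  }
  n <- length(patches)
  res <- list(
    patches = if (n) array(unlist(patches), dim = c(PATCH, PATCH, n)) else
      array(0, dim = c(PATCH, PATCH, 0)),
    masks = if (mode == "train" && n)
      array(unlist(masks), dim = c(PATCH, PATCH, n)) else NULL,
    provenance = if (n) dplyr::bind_rows(prov) else tibble::tibble())
  class(res) <- "patch_set"
  res
}

#' Combine patch sets
#'
#' @param ... `patch_set` objects.
#' @return a single `patch_set` with concatenated patches and provenance.
#' @export
bind_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "patch_set")) sets <- sets[[1]]
  n <- sum(vapply(sets, function(s) dim(s$patches)[3], 1L))
  patches <- array(0, dim = c(PATCH, PATCH, n))
  has_masks <- !is.null(sets[[1]]$masks)
  masks <- if (has_masks) array(FALSE, dim = c(PATCH, PATCH, n)) else NULL
  i <- 0L
  for (s in sets) {
    k <- dim(s$patches)[3]
    if (k == 0) next
    patches[, , i + seq_len(k)] <- s$patches
    if (has_masks) masks[, , i + seq_len(k)] <- s$masks
    i <- i + k
  }
  res <- list(patches = patches, masks = masks,
              provenance = dplyr::bind_rows(lapply(sets, `[[`, "provenance")))
  class(res) <- "patch_set"
  res
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set>", dim(x$patches)[3], "patches of",
      paste(dim(x$patches)[1:2], collapse = "x"),
      if (is.null(x$masks)) "(inference)" else "(with target masks)", "\n")
  invisible(x)
}

#' Binary cross-entropy loss
#'
#' `H = -(1/N) * sum(y log p + (1 - y) log(1 - p))`, with probabilities
#' clipped to `[eps, 1 - eps]`.
#'
#' @param y 0/1 (or logical) target vector.
#' @param p predicted probabilities, same length.
#' @param eps clipping constant.
#' @return non-negative scalar.
#' @export
binary_cross_entropy <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p))
    stop("target and prediction lengths differ", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  y <- as.numeric(y)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training configuration for the segmentation network
#'
#' Defaults follow the reference training recipe: plain SGD with constant
#' learning rate 0.01 and momentum 0.99, binary cross-entropy loss,
#' 50 epochs, one third of patches held out for validation, and the model
#' checkpoint with minimum validation loss retained.
#'
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param epochs training epochs.
#' @param val_fraction fraction of patches held out for validation.
#' @param batch_size mini-batch size.
#' @param seed integer seed (splitting, shuffling, dropout).
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.99, epochs = 50L,
                         val_fraction = 1 / 3, batch_size = 16L, seed = 1L) {
  stopifnot(lr > 0, val_fraction > 0, val_fraction < 1, epochs >= 1,
            batch_size >= 1)
  structure(list(lr = lr, momentum = momentum, epochs = as.integer(epochs),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

mean_mask_iou <- function(prob, truth, thr = 0.5) {
  pb <- prob >= thr
  inter <- sum(pb & truth); uni <- sum(pb | truth)
  if (uni == 0) 1 else inter / uni
}

#' Train the U-Net on a patch set
#'
#' Splits patches into training and validation subsets (seeded), runs
#' mini-batch SGD with momentum on the binary cross-entropy loss, tracks
#' per-epoch training/validation loss and validation IoU, and returns the
#' parameters of the epoch with minimum validation loss.
#'
#' @param patches a `patch_set` with target masks.
#' @param net a `unet` from [build_unet()]; the scaled-down default is
#'   suitable for phantom experiments.
#' @param config a [train_config()].
#' @return the trained `unet`, with `history` (tibble of epoch, train/val
#'   loss, val IoU) and `best_epoch` fields and `trained = TRUE`.
#' @export
train_unet <- function(patches, net = build_unet(depth = 2, base_filters = 16),
                       config = train_config()) {
  stopifnot(inherits(patches, "patch_set"), !is.null(patches$masks))
  n <- dim(patches$patches)[3]
  if (n < 2) stop("need at least 2 patches", call. = FALSE)
  set.seed(config$seed)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0)
    stop("validation split leaves no training patches", call. = FALSE)
  xs <- patches$patches; ys <- patches$masks * 1
  as_batch <- function(idx) {
    list(x = array(xs[, , idx], dim = c(PATCH, PATCH, 1, length(idx))),
         y = array(ys[, , idx], dim = c(PATCH, PATCH, 1, length(idx))))
  }
  val <- as_batch(val_idx)
  vel <- list()
  hist <- vector("list", config$epochs)
  best <- list(loss = Inf, params = NULL, state = NULL, epoch = NA_integer_)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    bl <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (b in bl) {
      ba <- as_batch(b)
      fw <- unet_forward(net, ba$x, training = TRUE, keep_cache = TRUE)
      loss <- binary_cross_entropy(ba$y, fw$prob)
      tr_loss <- tr_loss + loss * length(b)
      dlogits <- (fw$prob - ba$y) / length(ba$y)
      grads <- unet_backward(net, dlogits, fw$caches)
      st <- sgd_step(net, grads, vel, config$lr, config$momentum)
      net <- st$net; vel <- st$vel
    }
    tr_loss <- tr_loss / length(tr_idx)
    vp <- unet_forward(net, val$x)$prob
    val_loss <- binary_cross_entropy(val$y, vp)
    val_iou <- mean_mask_iou(vp, val$y > 0.5)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                    val_loss = val_loss, val_iou = val_iou)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = net$params,
                   state = as.list(net$state), epoch = epoch)
    }
  }
  net$params <- best$params
  for (nm in names(best$state)) net$state[[nm]] <- best$state[[nm]]
  net$history <- dplyr::bind_rows(hist)
  net$best_epoch <- best$epoch
  net$trained <- TRUE
  net$train_subjects <- unique(patches$provenance$subject)
  net
}

#' Predict whole-kidney masks for one frame of a series
#'
#' Runs the trained network on one centrally located patch per side per
#' slice, thresholds the probability maps at `threshold`, and reassembles
#' the patches into full-grid 3D masks, one per anatomical side. Under the
#' default radiological display convention the image-left half holds the
#' subject's right kidney.
#'
#' @param net a trained `unet`.
#' @param series a `dynamic_series`.
#' @param frame_index frame to segment (e.g. from
#'   [select_enhancement_frames()]).
#' @param threshold probability threshold for mask binarisation.
#' @param orientation `"radiological"` (default) or `"neurological"`.
#' @return list with logical 3D masks `left` and `right` (anatomical
#'   sides) on the series grid.
#' @export
predict_mask <- function(net, series, frame_index, threshold = 0.5,
                         orientation = c("radiological", "neurological")) {
  if (!isTRUE(net$trained))
    stop("network has not been trained", call. = FALSE)
  orientation <- match.arg(orientation)
  d <- dim(series$data)
  stopifnot(frame_index >= 1, frame_index <= d[4])
  vol <- series$data[, , , frame_index]
  ps <- extract_patches(vol, mode = "infer")
  np <- dim(ps$patches)[3]
  x <- array(ps$patches, dim = c(PATCH, PATCH, 1, np))
  prob <- unet_forward(net, x)$prob
  # patches without appreciable signal variation cannot contain kidney;
  # min-max normalisation would only amplify noise there, so they are
  # background by construction (the network never saw kidney-free patches)
  vol_range <- diff(range(vol))
  centre0 <- (PLANE - PATCH) %/% 2
  contrast <- vapply(seq_len(np), function(i) {
    pr <- ps$provenance[i, ]
    cols <- if (pr$side == "image_left") seq_len(PATCH) else
      PATCH + seq_len(PATCH)
    diff(range(fit_plane(vol[, , pr$slice])[cols,
                                            centre0 + seq_len(PATCH)]))
  }, 1.0)
  informative <- vol_range > 0 & contrast > 0.2 * vol_range
  full <- array(FALSE, dim = c(PLANE, PLANE, d[3]))
  for (i in seq_len(np)) {
    if (!informative[i]) next
    pr <- ps$provenance[i, ]
    cols <- if (pr$side == "image_left") seq_len(PATCH) else
      PATCH + seq_len(PATCH)
    full[cols, centre0 + seq_len(PATCH), pr$slice] <-
      prob[, , 1, i] >= threshold
  }
  # undo the centre crop/pad back to the acquisition grid
  out <- array(FALSE, dim = d[1:3])
  sx <- min(d[1], PLANE); sy <- min(d[2], PLANE)
  ox <- (PLANE - sx) %/% 2; oy <- (PLANE - sy) %/% 2
  ix <- (d[1] - sx) %/% 2; iy <- (d[2] - sy) %/% 2
  out[ix + seq_len(sx), iy + seq_len(sy), ] <-
    full[ox + seq_len(sx), oy + seq_len(sy), ]
  img_left <- out; img_left[(d[1] %/% 2 + 1):d[1], , ] <- FALSE
  img_right <- out; img_right[seq_len(d[1] %/% 2), , ] <- FALSE
  if (orientation == "radiological")
    list(left = img_right, right = img_left)
  else
    list(left = img_left, right = img_right)
}

#' Keep only the largest connected component of a mask
#'
#' Refinement step rejecting small extrarenal clusters: components are
#' identified (26-connectivity in 3D by default, with a 2D-per-slice
#' 8-connectivity option) and only the largest is retained. An empty input
#' yields an empty output with a warning; a size tie is resolved toward the
#' component discovered first in raster order (lowest coordinate) and
#' reported.
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (3D) or 6 (face-adjacent 3D); use
#'   `per_slice = TRUE` for slice-wise 2D refinement.
#' @param per_slice apply the refinement independently per slice.
#' @return logical array of the same shape.
#' @export
largest_component <- function(mask, connectivity = 26L, per_slice = FALSE) {
  stopifnot(length(dim(mask)) == 3)
  if (!any(mask)) {
    warning("empty mask; largest component undefined")
    return(mask)
  }
  if (per_slice) {
    for (z in seq_len(dim(mask)[3])) {
      sl <- mask[, , z, drop = FALSE]
      if (any(sl)) mask[, , z] <- largest_component(sl, connectivity)[, , 1]
    }
    return(mask)
  }
  lab <- label_components3d(as.logical(mask), dim(mask),
                            as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  winners <- which(sizes == max(sizes))
  if (length(winners) > 1)
    message("largest-component tie (", length(winners),
            " components of ", max(sizes),
            " voxels); keeping the lowest-coordinate one")
  keep <- winners[1]
  array(lab == keep, dim = dim(mask))
}
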