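test_that("enhancement-frame selection finds the cortical peak", {
  ph <- make_phantom(seg_phantom_config(seed = 1))
  sigc <- ph$curves$signal[ph$curves$compartment == "cortex"]
  k <- which.max(sigc)
  expect_equal(select_enhancement_frames(ph$series, n = 3),
               as.integer((k - 1):(k + 1)))
  expect_equal(select_enhancement_frames(ph$series, n = 1), k)
  # constant series: no enhancement
  arr <- array(100, c(8, 8, 2, 20))
  flat <- dynamic_series(arr, c(1, 1, 1), seq(0, 19) * 2.3, TR = 2.36,
                         TE = 0.8, flip_angle = 20, n_baseline = 4)
  expect_error(select_enhancement_frames(flat), "no enhancement")
  expect_error(select_enhancement_frames(ph$series, n = 80), "exceeds")
})

test_that("inference extraction yields two 96x96 patches per slice", {
  ph <- make_phantom(small_phantom_config(seed = 1))
  vol <- ph$series$data[, , , 20]
  ps <- extract_patches(vol, mode = "infer")
  nz <- dim(vol)[3]
  expect_equal(dim(ps$patches), c(96, 96, 2 * nz))
  expect_equal(sort(unique(ps$provenance$side)),
               c("image_left", "image_right"))
  expect_equal(nrow(ps$provenance), 2 * nz)
  expect_null(ps$masks)
})

test_that("training extraction respects the kidney-fraction constraint", {
  ph <- make_phantom(seg_phantom_config(seed = 2))
  f <- select_enhancement_frames(ph$series)[2]
  km <- ph$kidney_masks$left | ph$kidney_masks$right
  ps <- extract_patches(ph$series$data[, , , f], km, mode = "train",
                        n_offsets = 4, min_kidney_frac = 0.2, seed = 1,
                        subject = "sA")
  expect_gt(dim(ps$patches)[3], 0)
  expect_equal(dim(ps$patches), dim(ps$masks))
  # every training patch contains kidney pixels (at least the fraction)
  per_patch <- apply(ps$masks, 3, sum)
  expect_true(all(per_patch > 0))
  expect_true(all(c("subject", "session", "side", "slice", "frame",
                    "offset", "mirrored") %in% names(ps$provenance)))
  expect_true(all(ps$provenance$subject == "sA"))
  # mirroring is an involution
  p1 <- ps$patches[, , 1]
  expect_identical(p1[96:1, ][96:1, ], p1)
})

test_that("patch extraction is reproducible given the seed", {
  ph <- make_phantom(small_phantom_config(seed = 3))
  km <- ph$kidney_masks$left | ph$kidney_masks$right
  vol <- ph$series$data[, , , 20]
  a <- extract_patches(vol, km, mode = "train", seed = 9)
  b <- extract_patches(vol, km, mode = "train", seed = 9)
  expect_identical(a$patches, b$patches)
  expect_identical(a$provenance, b$provenance)
})

test_that("largest component keeps the biggest blob and handles edge cases", {
  m <- array(FALSE, c(12, 12, 3))
  m[1:5, 1:5, 1:2] <- TRUE            # 50 voxels
  m[10:11, 10:11, 3] <- TRUE          # 4 voxels
  out <- largest_component(m)
  expect_equal(sum(out), 50)
  expect_true(all(out[1:5, 1:5, 1:2]))
  # single blob is the identity
  single <- array(FALSE, c(5, 5, 2)); single[2:3, 2:3, 1] <- TRUE
  expect_identical(largest_component(single), single)
  # empty mask warns
  expect_warning(e <- largest_component(array(FALSE, c(3, 3, 3))), "empty")
  expect_equal(sum(e), 0)
  # two equal blobs: the lowest-coordinate one is kept, reported
  tie <- array(FALSE, c(10, 4, 1))
  tie[1:2, 1:2, 1] <- TRUE
  tie[8:9, 1:2, 1] <- TRUE
  expect_message(kept <- largest_component(tie), "tie")
  expect_true(all(kept[1:2, 1:2, 1]))
  expect_false(any(kept[8:9, 1:2, 1]))
})

test_that("training bookkeeping: history, checkpoint, reproducibility", {
  ph <- make_phantom(small_phantom_config(seed = 4))
  f <- select_enhancement_frames(ph$series)[2]
  km <- ph$kidney_masks$left | ph$kidney_masks$right
  ps <- extract_patches(ph$series$data[, , , f], km, mode = "train",
                        n_offsets = 2, seed = 1, subject = "sA")
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 5)
  tr <- train_unet(ps, build_unet(depth = 1, base_filters = 4, seed = 5), cfg)
  expect_equal(nrow(tr$history), 3)
  expect_equal(tr$best_epoch, which.min(tr$history$val_loss))
  expect_true(tr$trained)
  expect_lt(tail(tr$history$train_loss, 1), tr$history$train_loss[1])
  # identical seeds give identical training trajectories
  tr2 <- train_unet(ps, build_unet(depth = 1, base_filters = 4, seed = 5), cfg)
  expect_equal(tr$history$train_loss, tr2$history$train_loss,
               tolerance = 1e-12)
})

test_that("mask prediction contracts: grid, state, degenerate input", {
  ph <- make_phantom(small_phantom_config(seed = 4))
  f <- select_enhancement_frames(ph$series)[2]
  km <- ph$kidney_masks$left | ph$kidney_masks$right
  ps <- extract_patches(ph$series$data[, , , f], km, mode = "train",
                        n_offsets = 2, seed = 1)
  net <- build_unet(depth = 1, base_filters = 4, seed = 5)
  expect_error(predict_mask(net, ph$series, f), "trained")
  tr <- train_unet(ps, net, train_config(epochs = 2, batch_size = 8, seed = 5))
  masks <- predict_mask(tr, ph$series, f)
  expect_equal(dim(masks$left), dim(ph$series$data)[1:3])
  expect_equal(dim(masks$right), dim(ph$series$data)[1:3])
  expect_type(masks$left, "logical")
  # anatomical left sits on the image-right half under the radiological
  # convention: its support is confined to x > midline
  expect_equal(sum(masks$left[seq_len(32), , ]), 0)
  # all-background input yields empty masks (contrast guard)
  flat <- ph$series
  flat$data <- array(100, dim(flat$data))
  empty <- predict_mask(tr, flat, f)
  expect_equal(sum(empty$left) + sum(empty$right), 0)
})
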