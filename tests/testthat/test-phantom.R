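test_that("population AIF is causal, non-negative and linear in amplitude", {
  t <- seq(0, 170, by = 2.3)
  p <- aif_params(t_arrival = 18.4)
  aif <- population_aif(t, p)
  expect_true(all(aif$conc[t <= 18.4] == 0))
  expect_true(all(aif$conc >= 0))
  p2 <- p; p2$amplitude <- 2 * p$amplitude
  expect_equal(population_aif(t, p2)$conc, 2 * aif$conc)
  # all times before arrival -> all-zero curve
  expect_true(all(population_aif(c(0, 5, 10), p)$conc == 0))
  expect_error(aif_params(beta = -1), "positive")
})

test_that("AIF peak location matches a dense-grid brute-force search", {
  p <- aif_params(t_arrival = 18.4)
  tf <- seq(0, 120, by = 1e-3)
  dense <- population_aif(tf, p)
  t_peak <- tf[which.max(dense$conc)]
  # the gamma-variate peak sits near arrival + alpha*beta, pulled slightly
  # late by the washout term; the coarse-grid argmax must agree
  tc <- seq(0, 120, by = 0.1)
  coarse <- population_aif(tc, p)
  expect_lt(abs(tc[which.max(coarse$conc)] - t_peak), 0.1 + 1e-9)
  expect_gt(t_peak, p$t_arrival + p$alpha * p$beta - 1)
  expect_lt(t_peak, p$t_arrival + p$alpha * p$beta + 3)
})

test_that("concentration-to-signal maps zero to baseline and is monotone", {
  expect_equal(concentration_to_signal(rep(0, 5), 700, 1, 3.6, 2.36, 20),
               rep(700, 5))
  conc <- seq(0, 5, length.out = 50)
  sig <- concentration_to_signal(conc, 700, 1, 3.6, 2.36, 20)
  expect_true(all(diff(sig) > 0))   # T1-weighted regime
  expect_error(concentration_to_signal(c(-0.1, 0), 700, 1, 3.6, 2.36, 20),
               "negative")
})

test_that("noiseless phantom voxels reproduce the forward-model curves", {
  ph <- make_phantom(small_phantom_config(seed = 1, noise_sigma = 0))
  d <- dim(ph$series$data)
  m <- matrix(ph$series$data, prod(d[1:3]), d[4])
  for (k in 1:3) {
    rows <- m[which(ph$labels == k), , drop = FALSE]
    curve <- ph$curves$signal[ph$curves$compartment ==
                                c("cortex", "medulla", "pelvis")[k]]
    expect_lt(max(abs(sweep(rows, 2, curve))), 1e-12)
  }
  # cortex curve equals SPGR transform of the forward 2CFM concentration
  cfg <- ph$config
  conc <- forward_2cfm(cfg$cortex, ph$aif, times = ph$series$frame_times)
  s0 <- cfg$M0 * renodce:::spgr_rel(1 / cfg$T10[["cortex"]], cfg$TR,
                                    cfg$flip_angle)
  sig <- concentration_to_signal(conc, s0, cfg$T10[["cortex"]], cfg$r1,
                                 cfg$TR, cfg$flip_angle)
  expect_equal(ph$curves$signal[ph$curves$compartment == "cortex"], sig)
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- make_phantom(small_phantom_config(seed = 3, noise_sigma = 0.05))
  b <- make_phantom(small_phantom_config(seed = 3, noise_sigma = 0.05))
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$labels, b$labels)
  c <- make_phantom(small_phantom_config(seed = 4, noise_sigma = 0.05))
  expect_false(identical(a$series$data, c$series$data))
})

test_that("ground-truth SK-GFR equals cortex Ktrans times cortex volume", {
  ph <- make_phantom(small_phantom_config(seed = 2, noise_sigma = 0))
  # independent hand computation from the label map and voxel size
  for (s in c("left", "right")) {
    n_cortex <- sum(ph$labels == 1L & ph$kidney_masks[[s]])
    v_ml <- n_cortex * 2.2 * 2.2 * 3.0 / 1000
    row <- ph$truth[ph$truth$side == s, ]
    expect_equal(row$cortex_volume_ml, v_ml)
    expect_equal(row$sk_gfr_ml_min, ph$config$cortex$ktrans * v_ml)
  }
})

test_that("compartment curves are pairwise distinguishable", {
  # default dynamics (geometry does not affect the curves)
  ph <- make_phantom(small_phantom_config(seed = 1, noise_sigma = 0))
  cv <- ph$curves
  peak_t <- vapply(split(cv, cv$compartment),
                   function(g) g$time[which.max(g$conc)], 1.0)
  expect_lt(peak_t[["cortex"]], peak_t[["medulla"]])
  late <- cv$time > 150
  late_means <- vapply(split(cv[late, ], cv$compartment[late]),
                       function(g) mean(g$conc), 1.0)
  expect_gt(late_means[["pelvis"]], late_means[["cortex"]])
  expect_gt(late_means[["pelvis"]], late_means[["medulla"]])
  # baseline frames carry zero concentration
  nb <- ph$config$n_baseline
  expect_true(all(cv$conc[cv$time < nb * ph$config$frame_interval] == 0))
})

test_that("class mix approximates the 58/31/11 cortex/medulla/pelvis split", {
  ph <- make_phantom(seg_phantom_config(seed = 5))
  tab <- table(ph$labels[ph$labels > 0])
  frac <- as.numeric(tab) / sum(tab)
  expect_equal(frac, c(0.58, 0.31, 0.11), tolerance = 0.12)
})

test_that("invalid geometry is rejected", {
  expect_error(
    make_phantom(phantom_config(dim = c(32L, 32L, 6L),
                                semi_axes = c(20, 10, 2))),
    "geometry")
  expect_error(phantom_config(n_frames = 8L, n_baseline = 8L))
})

test_that("partial-volume mixing only alters boundary voxels", {
  cfg0 <- small_phantom_config(seed = 1, noise_sigma = 0)
  cfgp <- small_phantom_config(seed = 1, noise_sigma = 0, pv_width = 0.12)
  a <- make_phantom(cfg0); b <- make_phantom(cfgp)
  expect_identical(a$labels, b$labels)
  # interior voxels untouched, signals bounded by the pure curves
  expect_true(all(b$series$data >= min(a$series$data) - 1e-9))
  d4 <- dim(a$series$data)[4]
  diffmask <- apply(abs(a$series$data - b$series$data), 1:3, max) > 1e-9
  expect_true(any(diffmask))
  expect_lt(mean(diffmask), 0.2)   # only a thin boundary shell
})

test_that("gaussian noise has the configured magnitude and rician is non-negative", {
  cfg <- small_phantom_config(seed = 1, noise_sigma = 0)
  ph <- make_phantom(cfg)
  clean <- ph$series
  s0bar <- mean(clean$data[, , , 1:8])
  noisy <- add_noise(clean, sigma = 0.05, model = "gaussian", seed = 11)
  resid <- noisy$data - clean$data
  expect_gt(length(resid), 1e5)
  expect_equal(sd(resid), 0.05 * s0bar, tolerance = 0.02)
  # sigma = 0 is the identity
  expect_identical(add_noise(clean, 0, "gaussian", 1)$data, clean$data)
  ric <- add_noise(clean, 0.10, model = "rician", seed = 12)
  expect_true(all(ric$data >= 0))
  expect_error(add_noise(clean, 0.05, model = "poisson"))
})
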