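times <- seq(0, 170, by = 2.3)

test_that("vascular impulse response is a delayed unit-mass exponential", {
  expect_equal(virf(c(0, 0.5, 1.9), tg = 3, delta = 2), c(0, 0, 0))
  expect_equal(virf(2, tg = 3, delta = 2), 1 / 3)
  tf <- seq(2, 2 + 50 * 3, by = 1e-3)
  expect_equal(sum(virf(tf, 3, 2)) * 1e-3, 1, tolerance = 1e-3)
  expect_error(virf(1, tg = -1, delta = 0), "tg")
})

test_that("convolution with a unit step matches the closed form", {
  tg <- 5
  step_aif <- tibble::tibble(time = times, conc = rep(1, length(times)))
  got <- convolve_aif(step_aif, tg = tg, delta = 0)
  expect_lt(max(abs(got - (1 - exp(-times / tg)))), 1e-3)
  # zero input
  zero <- tibble::tibble(time = times, conc = rep(0, length(times)))
  expect_equal(convolve_aif(zero, 5, 2), rep(0, length(times)))
})

test_that("convolution conserves area for a compact bolus", {
  aif <- population_aif(seq(0, 600, by = 1), aif_params(t_arrival = 10))
  out <- convolve_aif(aif, tg = 4, delta = 2, dt = 0.05)
  a_in <- sum(aif$conc) * 1
  a_out <- sum(out) * 1
  expect_lt(abs(a_out - a_in) / a_in, 0.005)
  expect_true(all(out >= 0))
})

test_that("forward 2CFM matches the constant-AIF closed form", {
  c0 <- 2; tg <- 6; ktrans <- 0.3; vp <- 0.5
  aif <- tibble::tibble(time = times, conc = rep(c0, length(times)))
  got <- forward_2cfm(list(ktrans = ktrans, vp = vp, delta = 0, tg = tg), aif)
  expected <- (ktrans / 60) * c0 * (times - tg * (1 - exp(-times / tg))) +
    vp * c0 * (1 - exp(-times / tg))
  expect_lt(max(abs(got - expected)) / max(expected), 1e-3)
  # zero AIF
  zero <- tibble::tibble(time = times, conc = rep(0, length(times)))
  expect_equal(forward_2cfm(list(ktrans = 0.2, vp = 0.4, delta = 2, tg = 5),
                            zero), rep(0, length(times)))
})

test_that("late-time slope is linear in Ktrans", {
  # with a constant AIF the vascular term is flat at late times, so the
  # late-time slope is exactly Ktrans * c0 / 60 and doubles with Ktrans
  c0 <- 1.5
  times <- seq(0, 170, by = 2.3)
  aif <- tibble::tibble(time = times, conc = rep(c0, length(times)))
  slope_late <- function(ktrans) {
    y <- forward_2cfm(list(ktrans = ktrans, vp = 0.2, delta = 0, tg = 3),
                      aif)
    late <- times > 100
    unname(coef(lm(y[late] ~ times[late]))[2])
  }
  s1 <- slope_late(0.1); s2 <- slope_late(0.2)
  expect_equal(s2 / s1, 2, tolerance = 1e-3)
  expect_equal(s1, 0.1 * c0 / 60, tolerance = 1e-3)
})

test_that("SPGR conversion inverts exactly and is locally linear", {
  aif <- population_aif(times)
  ct <- forward_2cfm(list(ktrans = 0.2, vp = 0.4, delta = 2, tg = 5), aif)
  sig <- concentration_to_signal(ct, S0 = 800, T10 = 0.966, r1 = 3.6,
                                 TR = 2.36, flip_angle = 20)
  back <- signal_to_concentration(sig, n_baseline = 8, T10 = 0.966, r1 = 3.6,
                                  TR = 2.36, flip_angle = 20)
  expect_lt(max(abs(back - ct)), 1e-9)
  # flat signal -> zero concentration
  flat <- signal_to_concentration(rep(500, 20), 8, 0.966, 3.6, 2.36, 20)
  expect_equal(as.numeric(flat), rep(0, 20))
  # small-signal linearity: doubling (S - S0) about doubles concentration
  s0 <- 800
  c_small <- c(rep(0, 8), 0.05)
  s <- concentration_to_signal(c_small, s0, 0.966, 3.6, 2.36, 20)
  s2 <- s0 + 2 * (s - s0)
  c2 <- signal_to_concentration(s2, 8, 0.966, 3.6, 2.36, 20)
  expect_equal(c2[9] / c_small[9], 2, tolerance = 0.05)
  # saturation clipped with warning
  expect_warning(
    signal_to_concentration(c(rep(100, 4), 1e6), 4, 0.966, 3.6, 2.36, 20),
    "clip")
})

test_that("round trip over a concentration sweep is exact to 1e-9", {
  conc <- c(rep(0, 8), seq(0, 5, length.out = 60))
  sig <- concentration_to_signal(conc, 1000, 1.2, 3.6, 2.36, 20)
  back <- signal_to_concentration(sig, 8, 1.2, 3.6, 2.36, 20)
  expect_lt(max(abs(back - conc)), 1e-9)
})

test_that("noiseless 2CFM fit recovers the generating parameters", {
  aif <- population_aif(times)
  truth <- c(ktrans = 0.2, vp = 0.4, delta = 2, tg = 5)
  ct <- forward_2cfm(as.list(truth), aif)
  fit <- fit_2cfm(ct, aif)
  expect_lt(max(abs(fit$params - truth) / truth), 0.01)
  expect_true(fit$converged)
  # returned estimate within bounds and no lower RSS at any start
  b <- pk_bounds()
  expect_true(all(fit$params >= b$lower & fit$params <= b$upper))
  expect_true(all(fit$rss <= fit$start_rss + 1e-12))
})

test_that("degenerate measured curves are rejected", {
  aif <- population_aif(times)
  expect_error(fit_2cfm(rep(0, length(times)), aif), "enhancement")
  expect_error(fit_2cfm(1:5, aif, times = times[1:5]), "8 samples")
})

test_that("tidy and glance summarise a fit", {
  aif <- population_aif(times)
  ct <- forward_2cfm(list(ktrans = 0.2, vp = 0.4, delta = 2, tg = 5), aif)
  fit <- fit_2cfm(ct, aif)
  td <- tidy(fit)
  expect_equal(td$term, c("ktrans", "vp", "delta", "tg"))
  expect_true(all(c("estimate", "at_bound") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$rss >= 0)
})

test_that("mean cortex curve averages label-1 voxels framewise", {
  arr <- array(0, c(2, 2, 1, 3))
  arr[1, 1, 1, ] <- c(1, 2, 3)
  arr[2, 1, 1, ] <- c(3, 4, 5)
  arr[1, 2, 1, ] <- c(100, 100, 100)  # medulla, must be ignored
  ser <- dynamic_series(arr, c(1, 1, 1), c(0, 1, 2), TR = 2.36, TE = 0.8,
                        flip_angle = 20, n_baseline = 1)
  labels <- array(0L, c(2, 2, 1))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 1L; labels[1, 2, 1] <- 2L
  expect_equal(mean_cortex_curve(ser, labels), c(2, 3, 4))
  one <- labels; one[2, 1, 1] <- 0L
  expect_equal(mean_cortex_curve(ser, one), c(1, 2, 3))
  expect_error(mean_cortex_curve(ser, array(0L, c(2, 2, 1))), "cortex")
})

test_that("GFR arithmetic and BSA normalisation", {
  labels <- array(0L, c(10, 10, 10))
  labels[1:300] <- 1L   # 300 cortex voxels
  g <- compute_gfr(0.2, labels, spacing = c(10, 10, 10))  # 1 mL voxels
  expect_equal(g$cortex_volume_ml, 300)
  expect_equal(g$gfr_ml_min, 60)
  expect_false(g$bsa_normalized)
  gb <- compute_gfr(0.2, labels, c(10, 10, 10), body_surface_area = 1.73)
  expect_equal(gb$gfr_normalized, gb$gfr_ml_min)
  expect_error(compute_gfr(0.2, array(0L, c(2, 2, 2)), c(1, 1, 1)), "cortex")
})

test_that("AIF recovered from an aorta ROI matches the generating curve", {
  aif <- population_aif(times)
  sig <- concentration_to_signal(aif$conc, 900, T10 = 1.4, r1 = 3.6,
                                 TR = 2.36, flip_angle = 20)
  arr <- array(rep(sig, each = 8), c(2, 2, 2, length(times)))
  ser <- dynamic_series(arr, c(1, 1, 1), times, TR = 2.36, TE = 0.8,
                        flip_angle = 20, n_baseline = 8)
  roi <- array(TRUE, c(2, 2, 2))
  got <- aif_from_roi(ser, roi, T10_blood = 1.4, r1 = 3.6)
  expect_lt(max(abs(got$conc - aif$conc)), 1e-9)
  # single-voxel ROI behaves identically here (identical voxels)
  roi1 <- array(FALSE, c(2, 2, 2)); roi1[1] <- TRUE
  expect_equal(aif_from_roi(ser, roi1, 1.4, 3.6)$conc, got$conc)
  expect_error(aif_from_roi(ser, array(FALSE, c(2, 2, 2)), 1.4), "empty")
})
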