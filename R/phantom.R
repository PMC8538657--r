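# Synthetic 4D renal DCE-MRI phantom. Compartment concentration curves
# follow the same forward PK machinery the fitting stage assumes (2CFM for
# cortex and medulla; a late sigmoid accumulation surrogate for the
# excretory pelvis), converted to signal through the SPGR equation.

#' Default arterial input function parameters
#'
#' Gamma-variate first pass (peak-normalised shape `(u/(ab))^a exp(a - u/b)`)
#' plus a slower washout term, all scaled by one overall amplitude so the
#' curve is linear in `amplitude`.
#'
#' @param amplitude first-pass peak concentration (mmol/L).
#' @param alpha gamma-variate shape exponent.
#' @param beta gamma-variate time scale (s); the first-pass peak sits at
#'   `alpha * beta` seconds after arrival.
#' @param washout relative amplitude of the recirculation/washout term.
#' @param tau1 washout rise time constant (s).
#' @param tau2 washout decay time constant (s).
#' @param t_arrival bolus arrival time (s); the default matches injection
#'   just after an 8-frame baseline at 2.3 s spacing.
#' @return named list of AIF parameters.
#' @export
aif_params <- function(amplitude = 5, alpha = 3, beta = 4, washout = 0.3,
                       tau1 = 30, tau2 = 300, t_arrival = 8 * 2.3) {
  p <- list(amplitude = amplitude, alpha = alpha, beta = beta,
            washout = washout, tau1 = tau1, tau2 = tau2,
            t_arrival = t_arrival)
  if (any(unlist(p[c("alpha", "beta", "tau1", "tau2")]) <= 0) ||
      amplitude < 0 || washout < 0 || t_arrival < 0)
    stop("AIF shape parameters must be positive", call. = FALSE)
  p
}

#' Population arterial input function
#'
#' Evaluates a gamma-variate bolus plus slower washout at the given times.
#' Zero before the bolus arrival time, non-negative everywhere, and linear
#' in the overall amplitude.
#'
#' @param times sample times (s), non-decreasing, starting at >= 0.
#' @param params AIF parameters from [aif_params()].
#' @return tibble with columns `time` (s) and `conc` (mmol/L).
#' @examples
#' aif <- population_aif(seq(0, 170, by = 2.3))
#' @export
population_aif <- function(times, params = aif_params()) {
  stopifnot(!is.unsorted(times), all(times >= 0))
  u <- times - params$t_arrival
  peak <- params$alpha * params$beta
  # gamma-variate, peak-normalised: (u/(ab))^a * exp((ab - u)/b)
  shape <- ifelse(u <= 0, 0,
                  (u / peak)^params$alpha * exp((peak - u) / params$beta))
  wash <- ifelse(u <= 0, 0,
                 params$washout * (1 - exp(-u / params$tau1)) *
                   exp(-u / params$tau2))
  tibble::tibble(time = times,
                 conc = params$amplitude * (shape + wash))
}

#' Convert a concentration time-course to SPGR signal
#'
#' Forward spoiled gradient-echo transform: R1(t) = 1/T10 + r1 * C(t) and
#' S(t) = S0 * f(R1(t)) / f(1/T10), with f the steady-state SPGR signal
#' function. Exact inverse of [signal_to_concentration()].
#'
#' @param conc concentration (mmol/L), non-negative.
#' @param S0 baseline signal (arbitrary units).
#' @param T10 pre-contrast T1 (s).
#' @param r1 relaxivity (L mmol^-1 s^-1).
#' @param TR repetition time (ms).
#' @param flip_angle flip angle (degrees).
#' @return signal vector in the same units as `S0`.
#' @export
concentration_to_signal <- function(conc, S0, T10, r1, TR, flip_angle) {
  if (any(conc < 0)) stop("negative concentration", call. = FALSE)
  stopifnot(T10 > 0, TR > 0, flip_angle > 0, flip_angle < 90)
  S0 * spgr_rel(1 / T10 + r1 * conc, TR, flip_angle) /
    spgr_rel(1 / T10, TR, flip_angle)
}

#' Add measurement noise to a dynamic series
#'
#' Gaussian noise is additive N(0, sigma * S0bar) where S0bar is the mean
#' baseline signal of the series; Rician noise is the magnitude of the
#' complex signal with independent Gaussian components of that standard
#' deviation. Deterministic given `seed`.
#'
#' @param series a `dynamic_series`.
#' @param sigma noise standard deviation as a fraction of the mean baseline
#'   signal (>= 0).
#' @param model `"gaussian"` or `"rician"`.
#' @param seed integer seed.
#' @return the series with noisy intensities.
#' @export
add_noise <- function(series, sigma, model = c("gaussian", "rician"),
                      seed = 1L) {
  stopifnot(sigma >= 0)
  model <- match.arg(model)
  if (sigma == 0) return(series)
  d <- dim(series$data)
  s0bar <- mean(series$data[, , , seq_len(series$n_baseline)])
  sd <- sigma * s0bar
  set.seed(seed)
  n <- length(series$data)
  if (model == "gaussian") {
    series$data <- series$data + array(stats::rnorm(n, 0, sd), dim = d)
  } else {
    n1 <- array(stats::rnorm(n, 0, sd), dim = d)
    n2 <- array(stats::rnorm(n, 0, sd), dim = d)
    series$data <- sqrt((series$data + n1)^2 + n2^2)
  }
  series
}

#' Phantom configuration
#'
#' Defines the simulated acquisition (matrix, spacing, 74 frames at 2.3 s
#' with 8 pre-contrast baseline frames, SPGR TR/TE/flip angle), the kidney
#' geometry (two ellipsoids partitioned into a cortical shell, medullary
#' interior and central pelvis at a ~58/31/11 volume mix), the
#' per-compartment enhancement models and the noise model.
#'
#' Cortex and medulla follow the two-compartment filtration model; the
#' pelvis, which fills at the excretory phase, is modelled as a delayed
#' sigmoid accumulation with configurable onset and slope rather than by
#' filtration kinetics.
#'
#' @param dim matrix size (x, y, z) in voxels.
#' @param spacing voxel spacing (mm).
#' @param n_frames number of dynamic frames.
#' @param frame_interval frame spacing (s).
#' @param n_baseline pre-contrast baseline frames.
#' @param cortex,medulla 2CFM parameter lists (`ktrans` min^-1, `vp`,
#'   `delta` s, `tg` s); must lie within [pk_bounds()].
#' @param pelvis list with `amplitude` (mmol/L), `onset` (s, sigmoid
#'   midpoint) and `slope` (s, sigmoid time constant).
#' @param aif AIF parameters from [aif_params()].
#' @param T10 named vector of pre-contrast T1 (s) for cortex, medulla,
#'   pelvis, background.
#' @param r1 relaxivity (L mmol^-1 s^-1).
#' @param flip_angle flip angle (deg).
#' @param TR,TE repetition/echo time (ms).
#' @param M0 global equilibrium signal scale (arbitrary units).
#' @param background_scale relative brightness of non-renal background.
#' @param semi_axes kidney ellipsoid semi-axes (voxels, x/y/z).
#' @param r_pelvis,r_medulla normalised radii separating pelvis/medulla and
#'   medulla/cortex (defaults give the target 58/31/11 volume mix).
#' @param pv_width partial-volume transition width (in normalised-radius
#'   units). 0 (the default) gives pure compartment signals in every voxel;
#'   a positive width linearly mixes the signals of adjacent compartments
#'   (and background at the organ edge) across each boundary, emulating the
#'   partial volume effect that makes real boundary voxels ambiguous.
#'   Labels remain the majority compartment.
#' @param noise_sigma noise SD as fraction of mean baseline signal.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param seed integer seed.
#' @return validated list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(192L, 192L, 30L),
                           spacing = c(2.2, 2.2, 3.0),
                           n_frames = 74L,
                           frame_interval = 2.3,
                           n_baseline = 8L,
                           cortex = list(ktrans = 0.25, vp = 0.40,
                                         delta = 2.0, tg = 4.0),
                           medulla = list(ktrans = 0.08, vp = 0.20,
                                          delta = 3.5, tg = 15.0),
                           pelvis = list(amplitude = 3.0, onset = 100,
                                         slope = 15),
                           aif = aif_params(t_arrival = n_baseline * frame_interval),
                           T10 = c(cortex = 0.966, medulla = 1.412,
                                   pelvis = 1.6, background = 1.0),
                           r1 = 3.6,
                           flip_angle = 20,
                           TR = 2.36,
                           TE = 0.8,
                           M0 = 1000,
                           background_scale = 0.35,
                           semi_axes = NULL,
                           r_pelvis = 0.48,
                           r_medulla = 0.75,
                           pv_width = 0,
                           noise_sigma = 0.03,
                           noise_model = "gaussian",
                           seed = 1L) {
  if (is.null(semi_axes))
    semi_axes <- pmax(round(c(dim[1] * 0.095, dim[2] * 0.145, dim[3] / 3)), 1)
  cfg <- list(dim = as.integer(dim), spacing = spacing,
              n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              n_baseline = as.integer(n_baseline),
              cortex = cortex, medulla = medulla, pelvis = pelvis,
              aif = aif, T10 = T10, r1 = r1, flip_angle = flip_angle,
              TR = TR, TE = TE, M0 = M0,
              background_scale = background_scale,
              semi_axes = semi_axes, r_pelvis = r_pelvis,
              r_medulla = r_medulla, pv_width = pv_width,
              noise_sigma = noise_sigma, noise_model = noise_model,
              seed = as.integer(seed))
  stopifnot(cfg$n_baseline < cfg$n_frames, all(cfg$spacing > 0),
            cfg$noise_sigma >= 0, cfg$frame_interval > 0, pv_width >= 0,
            0 < r_pelvis, r_pelvis < r_medulla, r_medulla < 1)
  b <- pk_bounds()
  for (comp in list(cortex, medulla)) {
    v <- unlist(comp[c("ktrans", "vp", "delta", "tg")])
    if (any(v < b$lower) || any(v > b$upper))
      stop("compartment PK parameters outside physiological bounds",
           call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

# Pelvis surrogate: zero until bolus arrival, then a sigmoid accumulation
# re-anchored to zero at arrival so baseline frames carry no contrast.
pelvis_curve <- function(times, pelvis, t_arrival) {
  sig <- function(t) 1 / (1 + exp(-(t - pelvis$onset) / pelvis$slope))
  s0 <- sig(t_arrival)
  ifelse(times <= t_arrival, 0,
         pelvis$amplitude * (sig(times) - s0) / (1 - s0))
}

#' Generate a ground-truthed synthetic renal DCE-MRI series
#'
#' Places two ellipsoidal kidneys left and right of the volume midline,
#' partitions each into cortical shell, medullary interior and central
#' pelvis, evaluates the compartment concentration curves (2CFM for cortex
#' and medulla driven by the population AIF; sigmoid accumulation for the
#' pelvis), converts them to SPGR signal, and adds noise. All labelled
#' voxels of a compartment share the identical noiseless time-course, so
#' downstream stages can be validated against machine-precision ground
#' truth.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom`: `series` (a `dynamic_series`),
#'   `labels` (integer array, 0 background / 1 cortex / 2 medulla /
#'   3 pelvis), `kidney_masks` (list `left`/`right`, anatomical sides under
#'   the radiological display convention), `aif` (tibble), `curves`
#'   (tibble of noiseless compartment concentration and signal curves),
#'   `truth` (per-side cortex volume and SK-GFR) and the `config`.
#' @examples
#' ph <- make_phantom(phantom_config(dim = c(32, 32, 6), noise_sigma = 0))
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$dim; ax <- config$semi_axes
  if (ax[1] > d[1] / 4 || 2 * ax[2] > d[2] || 2 * ax[3] > d[3])
    stop("kidney geometry exceeds half-width of matrix", call. = FALSE)
  cx <- c(round(d[1] * 0.25), round(d[1] * 0.75))
  if (cx[1] + ax[1] >= cx[2] - ax[1])
    stop("left and right kidneys overlap", call. = FALSE)
  cy <- round(d[2] / 2); cz <- (d[3] + 1) / 2
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  labels <- array(0L, dim = d)
  masks <- list()
  rho_all <- array(Inf, dim = d)
  for (k in 1:2) {
    rho2 <- outer(outer(((x - cx[k]) / ax[1])^2, ((y - cy) / ax[2])^2, "+"),
                  ((z - cz) / ax[3])^2, "+")
    rho <- sqrt(rho2)
    lab <- array(0L, dim = d)
    lab[rho <= 1] <- 1L
    lab[rho <= config$r_medulla] <- 2L
    lab[rho <= config$r_pelvis] <- 3L
    labels[lab > 0] <- lab[lab > 0]
    masks[[k]] <- rho <= 1
    rho_all <- pmin(rho_all, rho)
  }
  # radiological display: image-left half (k = 1) is the subject's right
  kidney_masks <- list(right = masks[[1]], left = masks[[2]])

  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  aif <- population_aif(times, config$aif)
  conc <- list(
    cortex = forward_2cfm(config$cortex, aif, times = times),
    medulla = forward_2cfm(config$medulla, aif, times = times),
    pelvis = pelvis_curve(times, config$pelvis, config$aif$t_arrival))
  s0 <- vapply(c("cortex", "medulla", "pelvis"), function(cp)
    config$M0 * spgr_rel(1 / config$T10[[cp]], config$TR, config$flip_angle),
    1.0)
  sig <- lapply(c(cortex = "cortex", medulla = "medulla", pelvis = "pelvis"),
                function(cp) concentration_to_signal(
                  conc[[cp]], s0[[cp]], config$T10[[cp]], config$r1,
                  config$TR, config$flip_angle))
  bg_sig <- config$background_scale * config$M0 *
    spgr_rel(1 / config$T10[["background"]], config$TR, config$flip_angle)

  curve_mat <- rbind(rep(bg_sig, config$n_frames),
                     sig$cortex, sig$medulla, sig$pelvis)
  if (config$pv_width > 0) {
    # linear cross-fade of compartment signals across each boundary;
    # order outward: pelvis (3) -> medulla (2) -> cortex (1) -> background
    ramp <- function(rho, r0) pmin(pmax((r0 + config$pv_width / 2 - rho) /
                                          config$pv_width, 0), 1)
    w3 <- ramp(rho_all, config$r_pelvis)     # pelvis share
    w23 <- ramp(rho_all, config$r_medulla)   # pelvis + medulla share
    w123 <- ramp(rho_all, 1)                 # renal share vs background
    wm <- cbind(1 - w123,      # background
                w123 - w23,    # cortex
                w23 - w3,      # medulla
                w3)            # pelvis
    data <- wm %*% curve_mat
    dim(data) <- c(d, config$n_frames)
  } else {
    data <- curve_mat[as.integer(labels) + 1L, , drop = FALSE]
    dim(data) <- c(d, config$n_frames)
  }
  series <- dynamic_series(data, spacing = config$spacing,
                           frame_times = times, TR = config$TR,
                           TE = config$TE, flip_angle = config$flip_angle,
                           n_baseline = config$n_baseline)
  series <- add_noise(series, config$noise_sigma, config$noise_model,
                      seed = config$seed)

  vox_ml <- prod(config$spacing) / 1000
  truth <- tibble::tibble(
    side = c("right", "left"),
    cortex_volume_ml = c(sum(labels == 1L & masks[[1]]),
                         sum(labels == 1L & masks[[2]])) * vox_ml)
  truth$sk_gfr_ml_min <- config$cortex$ktrans * truth$cortex_volume_ml

  curves <- tibble::tibble(
    time = rep(times, 3),
    compartment = rep(c("cortex", "medulla", "pelvis"),
                      each = config$n_frames),
    conc = c(conc$cortex, conc$medulla, conc$pelvis),
    signal = c(sig$cortex, sig$medulla, sig$pelvis))

  structure(list(series = series, labels = labels,
                 kidney_masks = kidney_masks, aif = aif, curves = curves,
                 truth = truth, config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- x$config$dim
  cat("<phantom>", paste(d, collapse = "x"), "voxels,",
      x$config$n_frames, "frames @", x$config$frame_interval, "s;",
      sum(x$labels > 0), "renal voxels\n")
  print(x$truth)
  invisible(x)
}
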