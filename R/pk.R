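# Pharmacokinetic quantification: SPGR signal <-> concentration conversion,
# the two-compartment filtration model (2CFM), bounded NLLS fitting and
# single-kidney GFR computation.

# Relative SPGR steady-state signal for longitudinal rate R1 (1/s):
# sin(a) * (1 - E1) / (1 - cos(a) * E1), E1 = exp(-TR * R1).
spgr_rel <- function(R1, TR_ms, flip_deg) {
  a <- flip_deg * pi / 180
  E1 <- exp(-(TR_ms / 1000) * R1)
  sin(a) * (1 - E1) / (1 - cos(a) * E1)
}

#' Convert an SPGR signal time-course to contrast-agent concentration
#'
#' Inverts the spoiled gradient-echo steady-state signal equation. The
#' baseline signal S0 is the mean over the pre-contrast frames; the signal
#' ratio S/S0 is solved for E1 = exp(-TR * R1) and the concentration follows
#' from the linear relaxivity model R1(t) = 1/T10 + r1 * C(t).
#'
#' @param signal numeric vector of signal intensities (arbitrary units).
#' @param n_baseline number of pre-contrast baseline frames.
#' @param T10 pre-contrast T1 of the tissue (s).
#' @param r1 contrast-agent relaxivity (L mmol^-1 s^-1).
#' @param TR repetition time (ms).
#' @param flip_angle flip angle (degrees).
#' @return numeric concentration vector (mmol/L) with attributes `S0`
#'   (baseline signal) and `clipped` (TRUE if any sample hit the
#'   saturation limit of the inversion and was clipped, with a warning).
#' @seealso [concentration_to_signal()] for the forward transform.
#' @export
signal_to_concentration <- function(signal, n_baseline, T10, r1,
                                    TR, flip_angle) {
  stopifnot(n_baseline >= 1, n_baseline < length(signal),
            T10 > 0, TR > 0, flip_angle > 0, flip_angle < 90, r1 > 0)
  a <- flip_angle * pi / 180
  S0 <- mean(signal[seq_len(n_baseline)])
  if (S0 <= 0) stop("non-positive baseline signal", call. = FALSE)
  A0 <- spgr_rel(1 / T10, TR, flip_angle) / sin(a)  # (1-E10)/(1-cos E10)
  A <- A0 * signal / S0
  clipped <- FALSE
  # f(E1) = (1-E1)/(1-cos(a)E1) is invertible for E1 in (0,1), i.e. A in (0,1)
  hi <- A >= 1 - 1e-12
  if (any(hi)) {
    A[hi] <- 1 - 1e-12
    clipped <- TRUE
    warning("signal beyond SPGR saturation limit; concentration clipped")
  }
  lo <- A <= 0
  if (any(lo)) {
    A[lo] <- 1e-12
    clipped <- TRUE
    warning("non-positive signal ratio; concentration clipped")
  }
  E1 <- (1 - A) / (1 - A * cos(a))
  R1 <- -log(E1) / (TR / 1000)
  conc <- (R1 - 1 / T10) / r1
  attr(conc, "S0") <- S0
  attr(conc, "clipped") <- clipped
  conc
}

#' Vascular impulse response function
#'
#' Delayed, dispersed exponential kernel: zero before the delay `delta`,
#' then `(1/tg) * exp(-(t - delta)/tg)`. Integrates to one.
#'
#' @param t time (s), vector.
#' @param tg dispersion time constant (s), > 0.
#' @param delta delay interval (s).
#' @return kernel density values at `t`.
#' @export
virf <- function(t, tg, delta) {
  if (tg <= 0) stop("tg must be > 0", call. = FALSE)
  ifelse(t < delta, 0, exp(-(t - delta) / tg) / tg)
}

# Internal: convolve an AIF with the VIRF on a uniform fine grid.
# Exact for a piecewise-linear input: the exponential kernel admits the
# recursion y_n = a*y_{n-1} + (1-a)*x_n - b*(x_n - x_{n-1}) with
# a = exp(-dt/tg), b = tg/dt*(1-a) - a. Returns list(time, conc) on the
# fine grid.
convolve_aif_fine <- function(aif, tg, delta, dt = 0.1, t_max = max(aif$time)) {
  if (is.unsorted(aif$time, strictly = TRUE))
    stop("AIF times must be strictly increasing", call. = FALSE)
  tf <- seq(0, t_max, by = dt)
  x <- stats::approx(aif$time, aif$conc, xout = tf - delta,
                     yleft = 0, rule = 2)$y
  a <- exp(-dt / tg)
  b <- tg / dt * (1 - a) - a
  n <- length(tf)
  z <- (1 - a) * x[-1] - b * diff(x)
  y <- c(0, stats::filter(z, a, method = "recursive", init = x[1] * 0))
  y <- pmax(as.numeric(y), 0)
  list(time = tf, conc = y)
}

#' Convolve an arterial input function with the vascular impulse response
#'
#' Computes the intrarenal plasma concentration `Cp_kid = Cp_art (x) g(t)`
#' where `g` is the delayed dispersed exponential kernel of [virf()]. The
#' convolution is evaluated on an internal uniform fine grid (default
#' 0.1 s, exact for piecewise-linear input) and sampled back at `times`.
#'
#' @param aif data frame with columns `time` (s) and `conc` (mmol/L).
#' @param tg dispersion time constant (s).
#' @param delta delay (s).
#' @param times output sample times (s); defaults to the AIF times.
#' @param dt internal fine-grid spacing (s).
#' @return numeric vector of `Cp_kid` at `times`.
#' @export
convolve_aif <- function(aif, tg, delta, times = aif$time, dt = 0.1) {
  fine <- convolve_aif_fine(aif, tg, delta, dt = dt,
                            t_max = max(max(aif$time), max(times)))
  stats::approx(fine$time, fine$conc, xout = times, yleft = 0, rule = 2)$y
}

#' Default two-compartment filtration model parameter bounds
#'
#' Physiological box constraints used by [fit_2cfm()]: Ktrans in
#' \[0.05, 0.40\] min^-1, vp in \[0.2, 0.9\] (plasma volume fraction),
#' delay in \[1.0, 3.5\] s and dispersion time constant tg >= 0.02 s. The
#' dispersion constant has no stated physiological upper limit; a finite
#' optimiser bound (default 60 s) is required and configurable — beyond the
#' acquisition duration larger values are not identifiable.
#'
#' @param tg_upper finite upper optimiser bound for tg (s).
#' @return tibble with columns `param`, `lower`, `upper`.
#' @export
pk_bounds <- function(tg_upper = 60) {
  tibble::tibble(
    param = c("ktrans", "vp", "delta", "tg"),
    lower = c(0.05, 0.2, 1.0, 0.02),
    upper = c(0.40, 0.9, 3.5, tg_upper))
}

#' Forward two-compartment filtration model
#'
#' Tissue concentration as the sum of a filtration term — Ktrans times the
#' running integral of the intrarenal plasma concentration — and a vascular
#' term vp * Cp_kid(t), with Cp_kid the AIF convolved with the delayed
#' dispersed exponential impulse response. Ktrans is given in min^-1 and
#' converted internally; integration uses the trapezoidal rule on a uniform
#' fine grid.
#'
#' @param params named list or vector with `ktrans` (min^-1), `vp`
#'   (fraction), `delta` (s), `tg` (s).
#' @param aif data frame with columns `time`, `conc`.
#' @param times output sample times (s).
#' @param dt internal fine-grid spacing (s).
#' @return tissue concentration (mmol/L) at `times`.
#' @export
forward_2cfm <- function(params, aif, times = aif$time, dt = 0.1) {
  p <- as.list(params)
  fine <- convolve_aif_fine(aif, p$tg, p$delta, dt = dt,
                            t_max = max(max(aif$time), max(times)))
  y <- fine$conc
  n <- length(y)
  cum <- c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
  ct <- (p$ktrans / 60) * cum + p$vp * y
  stats::approx(fine$time, ct, xout = times, yleft = 0, rule = 2)$y
}

#' Fit the two-compartment filtration model by bounded least squares
#'
#' Minimises the sum of squared differences between the measured tissue
#' concentration curve and [forward_2cfm()] under the box constraints of
#' [pk_bounds()], using Levenberg--Marquardt with parameter bounds
#' (`minpack.lm::nls.lm`). The optimiser is local, so the fit is multi-started
#' from 17 deterministic interior points — the bound-box centre plus the
#' midpoints between the centre and each of the 16 bound-box corners — and
#' the lowest-RSS solution is returned.
#'
#' @param measured numeric tissue concentration curve (mmol/L).
#' @param aif data frame with columns `time`, `conc` (same time base).
#' @param times sample times of `measured` (s).
#' @param bounds bounds tibble as returned by [pk_bounds()].
#' @param dt internal fine-grid spacing (s).
#' @param at_bound_tol relative tolerance for flagging an estimate as
#'   lying on a bound.
#' @return object of class `pk_fit`: parameter estimates, residual sum of
#'   squares, convergence information, at-bound flags and the RSS at every
#'   start point.
#' @examples
#' aif <- population_aif(seq(0, 170, by = 2.3))
#' truth <- list(ktrans = 0.2, vp = 0.4, delta = 2, tg = 5)
#' ct <- forward_2cfm(truth, aif)
#' fit <- fit_2cfm(ct, aif)
#' tidy(fit)
#' @export
fit_2cfm <- function(measured, aif, times = aif$time, bounds = pk_bounds(),
                     dt = 0.1, at_bound_tol = 1e-3) {
  stopifnot(length(measured) == length(times))
  if (length(measured) < 8)
    stop("need at least 8 samples to fit the 2CFM", call. = FALSE)
  if (all(abs(measured) < 1e-12))
    stop("no enhancement in measured curve; cannot fit 2CFM", call. = FALSE)
  lower <- bounds$lower; upper <- bounds$upper
  names(lower) <- names(upper) <- bounds$param
  # pre-resample the AIF once; residual calls share the fine grid
  resid_fn <- function(par) {
    forward_2cfm(as.list(par), aif, times = times, dt = dt) - measured
  }
  qpt <- function(f) lower + f * (upper - lower)
  # bound-box centre plus the midpoints between the centre and each of the
  # 2^4 corners (quartile points): 17 deterministic starts
  corner_mids <- as.matrix(expand.grid(rep(list(c(0.25, 0.75)), 4)))
  starts <- c(list(qpt(rep(0.5, 4))),
              lapply(seq_len(nrow(corner_mids)),
                     function(i) qpt(corner_mids[i, ])))
  best <- NULL
  start_rss <- numeric(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[[i]]
    names(s) <- bounds$param
    start_rss[i] <- sum(resid_fn(s)^2)
    fit <- minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  est <- best$fit$par
  rng <- upper - lower
  at_bound <- (est - lower) < at_bound_tol * rng |
    (upper - est) < at_bound_tol * rng
  structure(list(params = est,
                 rss = best$rss,
                 converged = best$fit$info %in% 1:4,
                 n_iter = best$fit$niter,
                 at_bound = at_bound,
                 start_rss = start_rss,
                 bounds = bounds),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> 2CFM estimates:\n")
  print(round(x$params, 4))
  cat("RSS:", format(x$rss, digits = 4),
      "| converged:", x$converged,
      "| at bound:", paste(names(x$params)[x$at_bound], collapse = ", "),
      "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 2CFM fit into one row per parameter
#'
#' @param x a `pk_fit` object.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`, `lower`, `upper`,
#'   `at_bound`.
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unname(x$params),
                 lower = x$bounds$lower,
                 upper = x$bounds$upper,
                 at_bound = unname(x$at_bound))
}

#' One-row fit summary of a 2CFM fit
#'
#' @param x a `pk_fit` object.
#' @param ... unused.
#' @return tibble with `rss`, `converged`, `n_iter`.
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n_iter = x$n_iter)
}

#' Mean signal time-course over the segmented cortex
#'
#' @param series a `dynamic_series`.
#' @param labels compartment label map (integer array on the series grid;
#'   1 = cortex).
#' @return numeric vector, one value per frame.
#' @export
mean_cortex_curve <- function(series, labels) {
  d <- dim(series$data)
  stopifnot(all(dim(labels) == d[1:3]))
  idx <- which(labels == 1L)
  if (length(idx) == 0)
    stop("no cortex voxels in label map", call. = FALSE)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  colMeans(m[idx, , drop = FALSE])
}

#' Single-kidney GFR from cortical Ktrans and cortex volume
#'
#' SK-GFR = Ktrans (min^-1) x cortex volume (mL), the cortex volume being the
#' cortex voxel count times the voxel volume. When a body surface area is
#' supplied the value is additionally normalised to 1.73 m^2.
#'
#' @param ktrans cortical transfer constant (min^-1), > 0.
#' @param labels compartment label map (1 = cortex).
#' @param spacing voxel spacing (mm, length 3).
#' @param body_surface_area optional body surface area (m^2).
#' @return object of class `gfr_result`: a one-row tibble with
#'   `gfr_ml_min`, `gfr_normalized` (mL/min/1.73 m^2, `NA` when no BSA was
#'   given), `cortex_volume_ml`, `ktrans`, `bsa_normalized` flag.
#' @export
compute_gfr <- function(ktrans, labels, spacing, body_surface_area = NULL) {
  stopifnot(ktrans > 0, length(spacing) == 3, all(spacing > 0))
  n_cortex <- sum(labels == 1L)
  if (n_cortex == 0)
    stop("label map contains no cortex voxels", call. = FALSE)
  vol_ml <- n_cortex * prod(spacing) / 1000
  gfr <- ktrans * vol_ml
  res <- tibble::tibble(
    gfr_ml_min = gfr,
    gfr_normalized = if (is.null(body_surface_area)) NA_real_ else
      gfr * 1.73 / body_surface_area,
    cortex_volume_ml = vol_ml,
    ktrans = ktrans,
    bsa_normalized = !is.null(body_surface_area))
  class(res) <- c("gfr_result", class(res))
  res
}

#' Arterial input function from an aorta region of interest
#'
#' Averages the ROI signal per frame and converts it to plasma
#' concentration with [signal_to_concentration()] using blood T1.
#' No hematocrit correction is applied by default; supply
#' `hematocrit` to scale whole-blood concentration to plasma.
#'
#' @param series a `dynamic_series`.
#' @param roi logical 3D array on the series grid (aorta voxels).
#' @param T10_blood pre-contrast blood T1 (s).
#' @param r1 relaxivity (L mmol^-1 s^-1).
#' @param hematocrit optional hematocrit fraction; when given the curve is
#'   divided by (1 - hematocrit).
#' @return tibble with columns `time`, `conc`.
#' @export
aif_from_roi <- function(series, roi, T10_blood = 1.4, r1 = 3.6,
                         hematocrit = NULL) {
  d <- dim(series$data)
  stopifnot(all(dim(roi) == d[1:3]))
  idx <- which(roi)
  if (length(idx) == 0) stop("empty aorta ROI", call. = FALSE)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  sig <- colMeans(m[idx, , drop = FALSE])
  conc <- signal_to_concentration(sig, series$n_baseline, T10_blood, r1,
                                  series$TR, series$flip_angle)
  if (!is.null(hematocrit)) conc <- conc / (1 - hematocrit)
  tibble::tibble(time = series$frame_times, conc = as.numeric(conc))
}
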