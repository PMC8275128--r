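#' Stimulation and acquisition protocol
#'
#' Frame structure of the time-resolved recordings: frames every 5 ms (3 ms
#' acquisition + 2 ms readout), four resting frames before the first
#' stimulus, 42 frames for a twitch (single stimulus at t = 0) and 68 frames
#' for a tetanus (130 Hz train for 100 ms, stimuli at 0 ... 100 ms). Frame
#' times are the mid-points of the 3 ms acquisition windows, so the resting
#' frames are centred at -18.5, -13.5, -8.5 and -3.5 ms.
#'
#' @param mode `"twitch"` or `"tetanus"`.
#' @param n_frames number of frames; defaults to 42 (twitch) or 68 (tetanus).
#' @param frame_period_ms frame repeat period (5 ms).
#' @param acquisition_ms acquisition window within each frame (3 ms).
#' @param n_resting_frames frames acquired before the first stimulus (4).
#' @param seed default RNG seed attached to the protocol.
#' @return An object of class `"acquisition_protocol"` with the fields above
#'   plus `t_ms` (frame mid-times) and `stimulus_times` (ms).
#' @examples
#' p <- acquisition_protocol("tetanus")
#' head(p$t_ms); range(p$stimulus_times)
#' @export
acquisition_protocol <- function(mode = c("twitch", "tetanus"),
                                 n_frames = NULL, frame_period_ms = 5,
                                 acquisition_ms = 3, n_resting_frames = 4L,
                                 seed = 0L) {
  mode <- match.arg(mode)
  if (is.null(n_frames)) n_frames <- if (mode == "twitch") 42L else 68L
  stim <- if (mode == "twitch") 0 else seq(0, 100, by = 1000 / 130)
  # first acquisition starts so that n_resting_frames precede the stimulus
  t0 <- -n_resting_frames * frame_period_ms + acquisition_ms / 2
  t_ms <- t0 + (seq_len(n_frames) - 1) * frame_period_ms
  stopifnot(sum(t_ms < min(stim)) == n_resting_frames)
  structure(list(mode = mode, n_frames = as.integer(n_frames),
                 frame_period_ms = frame_period_ms,
                 acquisition_ms = acquisition_ms,
                 n_resting_frames = as.integer(n_resting_frames),
                 stimulus_times = stim, t_ms = t_ms, seed = as.integer(seed)),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %s: %d frames every %g ms, %d resting, %d stimuli\n",
              x$mode, x$n_frames, x$frame_period_ms, x$n_resting_frames,
              length(x$stimulus_times)))
  invisible(x)
}

#' Sigmoidal rise-and-fall kinetics of a generated signal
#'
#' Generative time course used by the synthetic-data module: the product of
#' a rising and a falling logistic,
#' `v(t) = baseline + (plateau - baseline) * rise(t) * fall(t)`, with
#' `rise(t) = 1/(1 + exp(-k (t - t_half_rise)))` and
#' `fall(t) = 1/(1 + exp(+k (t - t_half_fall)))`. The two half-times are
#' independent; measurement noise is additive Gaussian with standard
#' deviation `noise_sd * |plateau - baseline|`.
#'
#' @param baseline,plateau signal levels before and during full activation.
#' @param t_half_rise,t_half_fall half-times (ms, > 0 separation required in
#'   practice); referenced to the same clock as the protocol frame times.
#' @param steepness logistic steepness `k` (per ms).
#' @param noise_sd noise level as a fraction of `|plateau - baseline|`.
#' @return An object of class `"signal_kinetics"`.
#' @export
signal_kinetics <- function(baseline, plateau, t_half_rise, t_half_fall,
                            steepness = 0.15, noise_sd = 0) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (steepness <= 0) stop("`steepness` must be positive")
  structure(list(baseline = baseline, plateau = plateau,
                 t_half_rise = t_half_rise, t_half_fall = t_half_fall,
                 steepness = steepness, noise_sd = noise_sd),
            class = "signal_kinetics")
}

# noiseless product-of-sigmoids time course
kinetics_value <- function(kin, t_ms) {
  rise <- stats::plogis(kin$steepness * (t_ms - kin$t_half_rise))
  fall <- stats::plogis(-kin$steepness * (t_ms - kin$t_half_fall))
  kin$baseline + (kin$plateau - kin$baseline) * rise * fall
}

#' Synthetic M3 axial profile from the interference model
#'
#' Evaluates the forward interference model on the requested grid, convolves
#' with the point-spread function, and applies multiplicative Gaussian noise:
#' `I_obs = I * (1 + noise_fraction * e)`, `e ~ N(0,1)`. The per-point
#' standard deviation is `noise_fraction * I` (the noiseless intensity); with
#' `noise_fraction = 0` the profile is exact and carries no sd column.
#'
#' @param model a [tf_model()]; its `y` scales the profile.
#' @param psf_sigma point-spread sigma, nm^-1.
#' @param grid numeric vector of reciprocal spacings (uniform, covering the
#'   M3 window), or `NULL` for the default 30-point window grid.
#' @param noise_fraction relative noise level (>= 0).
#' @param seed RNG seed.
#' @return An [xrd_profile()].
#' @examples
#' m <- tf_model(90.58, 14.552, 1, 49, y = 2)
#' p <- generate_m3_profile(m, noise_fraction = 0.01, seed = 1)
#' @export
generate_m3_profile <- function(model, psf_sigma = psf_sigma_reciprocal(),
                                grid = NULL, noise_fraction = 0, seed = 0L) {
  if (is.null(grid))
    grid <- seq(xrd_windows()$m3_axial[1], xrd_windows()$m3_axial[2],
                length.out = 30)
  if (noise_fraction < 0) stop("`noise_fraction` must be >= 0")
  win <- xrd_windows()$m3_axial
  if (min(grid) > win[1] + 1e-12 || max(grid) < win[2] - 1e-12)
    stop("grid must cover the M3 window ", win[1], "-", win[2], " nm^-1")
  grid_step(grid, "generate_m3_profile")
  I <- m3_forward(grid, model, psf_sigma)
  if (noise_fraction == 0) return(xrd_profile(grid, I))
  obs <- with_seed(seed, I * (1 + noise_fraction * stats::rnorm(length(I))))
  xrd_profile(grid, obs, sd = noise_fraction * I)
}

#' Synthetic mixed myosin/actin layer-line profile
#'
#' Two Gaussians of the given integrated intensities centred at the
#' reciprocal spacings of the myosin (ML1, `1/s_ml1`) and actin (AL1,
#' `1/s_al1`) first layer lines, sharing one axial width, plus a smooth
#' polynomial background and additive Gaussian noise.
#'
#' @param s_ml1,s_al1 layer-line spacings in nm (must be distinct).
#' @param i_ml1,i_al1 integrated intensities (areas) of the two components.
#' @param axial_width shared Gaussian sigma, nm^-1.
#' @param background polynomial coefficients (constant first) evaluated in
#'   the axial coordinate; default none.
#' @param noise_sd additive noise sd (intensity units).
#' @param grid axial grid, default 81 points over the layer-line window.
#' @param seed RNG seed.
#' @return An [xrd_profile()]; `sd` is set to `noise_sd` when positive.
#' @export
generate_layerline_profile <- function(s_ml1 = 43.0, s_al1 = 36.6,
                                       i_ml1 = 1, i_al1 = 1,
                                       axial_width = 0.0012,
                                       background = 0, noise_sd = 0,
                                       grid = NULL, seed = 0L) {
  if (abs(s_ml1 - s_al1) < 1e-9)
    stop("identical layer-line spacings: deconvolution non-identifiable")
  if (axial_width <= 0) stop("`axial_width` must be positive")
  if (is.null(grid))
    grid <- seq(xrd_windows()$layerline_axial[1],
                xrd_windows()$layerline_axial[2], length.out = 81)
  bg <- rowSums(vapply(seq_along(background),
                       function(k) background[k] * grid^(k - 1),
                       numeric(length(grid))))
  I <- i_ml1 * stats::dnorm(grid, 1 / s_ml1, axial_width) +
       i_al1 * stats::dnorm(grid, 1 / s_al1, axial_width) + bg
  if (noise_sd == 0) return(xrd_profile(grid, I))
  obs <- with_seed(seed, I + noise_sd * stats::rnorm(length(I)))
  xrd_profile(grid, obs, sd = rep(noise_sd, length(grid)))
}

#' Synthetic layer-line time series
#'
#' Builds a frame-resolved series of mixed ML1/AL1 layer-line profiles whose
#' component intensities follow product-of-sigmoids time courses, for
#' testing the global deconvolution. Noise is additive per profile point
#' with sd equal to `noise_sd` times the resting ML1 peak height.
#'
#' @param protocol an [acquisition_protocol()].
#' @param ml1,al1 [signal_kinetics()] for the ML1 and AL1 integrated
#'   intensities (their `noise_sd` fields are ignored; see `noise_sd`).
#' @param s_ml1,s_al1,axial_width true spacings (nm) and shared width.
#' @param noise_sd relative additive noise level.
#' @param seed RNG seed (defaults to the protocol seed).
#' @return A list with `series` (an [xrd_series()]) and `truth` (the
#'   generative parameters, including per-frame intensities).
#' @export
generate_layerline_series <- function(protocol, ml1, al1,
                                      s_ml1 = 43.0, s_al1 = 36.6,
                                      axial_width = 0.0012,
                                      noise_sd = 0, seed = NULL) {
  if (is.null(seed)) seed <- protocol$seed
  t_ms <- protocol$t_ms
  iml <- kinetics_value(ml1, t_ms)
  ial <- kinetics_value(al1, t_ms)
  peak0 <- max(iml[1], ial[1]) * stats::dnorm(0, 0, axial_width)
  abs_sd <- noise_sd * peak0
  profs <- with_seed(seed, lapply(seq_along(t_ms), function(i) {
    p <- generate_layerline_profile(s_ml1, s_al1, iml[i], ial[i], axial_width,
                                    noise_sd = 0)
    if (abs_sd > 0)
      p <- xrd_profile(p$R, p$intensity + abs_sd * stats::rnorm(nrow(p)),
                       sd = rep(abs_sd, nrow(p)))
    p
  }))
  list(series = xrd_series(profs, t_ms, protocol),
       truth = list(s_ml1 = s_ml1, s_al1 = s_al1, axial_width = axial_width,
                    i_ml1 = iml, i_al1 = ial, noise_sd = abs_sd))
}

#' Synthetic scalar time series for twitch/tetanus protocols
#'
#' Generates frame-resolved scalar observables (force and X-ray parameters)
#' whose underlying time courses are products of rising and falling logistic
#' sigmoids, sampled at the protocol frame mid-times with additive Gaussian
#' noise. The generative ground truth is returned alongside so parameter
#' recovery is a one-liner.
#'
#' @param protocol an [acquisition_protocol()].
#' @param kinetics named list of [signal_kinetics()], one per signal (e.g.
#'   `force`, `s_m3`, `i_ml1`); see [default_kinetics()].
#' @param seed RNG seed (defaults to the protocol seed).
#' @return An object of class `"xr_sim"`: `traces` (data frame with `frame`,
#'   `t_ms` and one column per signal), `truth` (noiseless values and the
#'   kinetics used), `protocol`.
#' @examples
#' sim <- generate_timeseries(acquisition_protocol("tetanus"),
#'                            default_kinetics("tetanus"), seed = 1)
#' head(sim$traces)
#' @export
generate_timeseries <- function(protocol, kinetics, seed = NULL) {
  if (!length(names(kinetics)) || any(names(kinetics) == ""))
    stop("`kinetics` must be a named list of signal_kinetics")
  if (is.null(seed)) seed <- protocol$seed
  t_ms <- protocol$t_ms
  clean <- vapply(kinetics, kinetics_value, numeric(length(t_ms)), t_ms = t_ms)
  noisy <- with_seed(seed, {
    out <- clean
    for (j in seq_along(kinetics)) {
      kin <- kinetics[[j]]
      s <- kin$noise_sd * abs(kin$plateau - kin$baseline)
      if (s > 0) out[, j] <- out[, j] + s * stats::rnorm(length(t_ms))
    }
    out
  })
  traces <- data.frame(frame = seq_along(t_ms), t_ms = t_ms, noisy)
  truth <- data.frame(frame = seq_along(t_ms), t_ms = t_ms, clean)
  structure(list(traces = traces, truth = truth, kinetics = kinetics,
                 protocol = protocol),
            class = "xr_sim")
}

#' Study-condition default kinetics for the generator
#'
#' Baselines, plateaus and half-times of the main observables, taken from
#' the resting and peak-force values and the measured activation/relaxation
#' half-times of the twitch and tetanus protocols (intensities normalised to
#' rest; relaxation half-times are absolute frame-clock times, i.e.
#' referenced half-time + last stimulus for the tetanus).
#'
#' @param mode `"twitch"` or `"tetanus"`.
#' @param noise_sd noise fraction applied to every signal.
#' @return Named list of [signal_kinetics()].
#' @export
default_kinetics <- function(mode = c("twitch", "tetanus"), noise_sd = 0.02) {
  mode <- match.arg(mode)
  k <- function(b, p, r, f) signal_kinetics(b, p, r, f, noise_sd = noise_sd)
  if (mode == "tetanus")
    list(force = k(0, 273, 17.0, 127.3),
         s_m6  = k(7.173, 7.283, 8.1, 132.4),
         s_m3  = k(14.339, 14.535, 10.9, 133.6),
         i_ml1 = k(1, 0.09, 8.6, 141.8),
         i_al1 = k(1, 2.66, 15.3, 123.4),
         ratio_11_10 = k(0.41, 1.77, 11.3, 130.3),
         d_10  = k(35.32, 35.74, 11, 135),
         sl    = k(2.41, 2.13, 10, 140))
  else
    list(force = k(0, 68, 9, 24.4),
         s_m6  = k(7.173, 7.241, 7, 25.7),
         s_m3  = k(14.344, 14.425, 9, 20.1),
         i_ml1 = k(1, 0.28, 8, 29.4),
         i_al1 = k(1, 0.74, 12, 25),
         ratio_11_10 = k(0.39, 0.93, 10, 28.4),
         d_10  = k(35.07, 35.44, 10, 26),
         sl    = k(2.37, 2.38, 10, 25))
}

#' Read a generator configuration from YAML
#'
#' Convenience front end for scripted generation: a YAML file with a
#' `protocol` block (fields of [acquisition_protocol()]) and a `kinetics`
#' block (one named entry per signal with the fields of
#' [signal_kinetics()]).
#'
#' @param file path to a YAML file.
#' @return A list with `protocol` and `kinetics` ready for
#'   [generate_timeseries()].
#' @export
read_sim_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$protocol$mode)) stop("config needs protocol: mode")
  protocol <- do.call(acquisition_protocol, cfg$protocol)
  kinetics <- lapply(cfg$kinetics, function(x) do.call(signal_kinetics, x))
  list(protocol = protocol, kinetics = kinetics)
}
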