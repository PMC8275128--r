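#' Sigmoid half-time of an activation or relaxation transient
#'
#' Fits a 4-parameter logistic
#' `v(t) = baseline + amplitude / (1 + exp(-k (t - t0)))` to a scalar trace
#' sampled on the 5-ms frame grid and reports the half-time: the time at
#' which the fitted curve crosses the midpoint between its baseline and
#' plateau (the logistic midpoint `t0`), minus `reference_time`. Activation
#' and twitch-relaxation half-times are referenced to the first stimulus
#' (time 0); tetanus-relaxation half-times to the last stimulus (100 ms).
#' The steepness is bounded to 0.05-5 per ms to keep ill-conditioned fits
#' finite.
#'
#' @param t time, ms (frame mid-times).
#' @param value observed signal.
#' @param phase `"rise"` or `"fall"` (sign of the fitted amplitude).
#' @param reference_time subtracted from the fitted midpoint (ms).
#' @param window optional `c(lo, hi)` time window (ms) to fit, e.g. the
#'   rising phase only.
#' @return An object of class `"halftime_fit"`: `t_half` (ms, referenced),
#'   `t0`, `baseline`, `amplitude`, `steepness`, `converged`, `flag`
#'   (`"ok"` or `"nonmonotone"`), and the `fitted` values.
#' @examples
#' t <- seq(-18.5, 96.5, by = 5)
#' y <- 100 * plogis(0.3 * (t - 17))
#' fit_halftime(t, y, "rise")$t_half
#' @export
fit_halftime <- function(t, value, phase = c("rise", "fall"),
                         reference_time = 0, window = NULL) {
  phase <- match.arg(phase)
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; value <- value[keep]
  }
  if (length(t) < 4) stop("need at least 4 points spanning the transition")
  rng <- range(value)
  amp0 <- diff(rng) * if (phase == "rise") 1 else -1
  b0 <- if (phase == "rise") rng[1] else rng[2]
  mid <- b0 + amp0 / 2
  t0 <- t[which.min(abs(value - mid))]
  fit <- minpack.lm::nls.lm(
    par = c(b = b0, a = amp0, t0 = t0, k = 0.2),
    lower = c(-Inf, if (phase == "rise") 0 else -Inf, min(t), 0.05),
    upper = c(Inf, if (phase == "rise") Inf else 0, max(t), 5),
    fn = function(p) value - (p[["b"]] + p[["a"]] *
                                stats::plogis(p[["k"]] * (t - p[["t0"]]))),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-12))
  p <- fit$par
  fitted <- p[["b"]] + p[["a"]] * stats::plogis(p[["k"]] * (t - p[["t0"]]))
  # flag clear non-monotone traces: fraction of variance off the fit
  r2 <- 1 - sum((value - fitted)^2) / max(sum((value - mean(value))^2), 1e-300)
  structure(list(t_half = p[["t0"]] - reference_time,
                 t0 = p[["t0"]], baseline = p[["b"]], amplitude = p[["a"]],
                 steepness = p[["k"]],
                 converged = fit$info %in% 1:4,
                 flag = if (r2 < 0.8) "nonmonotone" else "ok",
                 fitted = fitted),
            class = "halftime_fit")
}

#' @export
print.halftime_fit <- function(x, ...) {
  cat(sprintf("<halftime_fit> t_half = %.2f ms (k = %.3f /ms)%s\n",
              x$t_half, x$steepness, if (x$flag == "ok") "" else "  [nonmonotone]"))
  invisible(x)
}

#' Percentage change of a parameter relative to rest
#'
#' `100 * (active - rest) / rest`, the convention used for spacing changes
#' (e.g. the ~1.5% increase of the M6 spacing at the tetanus plateau).
#'
#' @param rest_value resting value (> 0).
#' @param active_value active value.
#' @return Percent change.
#' @examples
#' percent_change(7.173, 7.283)  # ~1.53
#' @export
percent_change <- function(rest_value, active_value) {
  if (any(rest_value <= 0)) stop("`rest_value` must be positive")
  100 * (active_value - rest_value) / rest_value
}

#' Reflection amplitude from normalised intensity
#'
#' The fraction of molecules in a given conformation is proportional to the
#' amplitude of an X-ray reflection, the square root of its intensity:
#' `A = sqrt(I/I_rest)`.
#'
#' @param i_norm normalised intensity (>= 0).
#' @return `sqrt(i_norm)`.
#' @export
amplitude_from_intensity <- function(i_norm) {
  if (any(i_norm < 0)) stop("normalised intensity must be >= 0")
  sqrt(i_norm)
}

#' Muscle cross-sectional area from wet weight
#'
#' `CSA = 2 * W_MW / (rho * L0)`, the standard estimate for a whole muscle
#' of wet weight `W_MW`, density `rho` and optimal length `L0` (the factor 2
#' accounts for fibre obliquity/architecture). With weight in mg, density in
#' g cm^-3 and length in mm the result is directly in mm^2.
#'
#' @param muscle_wet_weight_mg wet weight, mg.
#' @param density_g_cm3 muscle density, g cm^-3 (1.06).
#' @param l0_mm optimal muscle length, mm.
#' @return Cross-sectional area, mm^2.
#' @examples
#' cross_sectional_area(9.6, 1.06, 12.1)  # ~1.50 mm^2
#' @export
cross_sectional_area <- function(muscle_wet_weight_mg, density_g_cm3 = 1.06,
                                 l0_mm) {
  if (any(c(muscle_wet_weight_mg, density_g_cm3, l0_mm) <= 0))
    stop("all inputs must be positive")
  2 * muscle_wet_weight_mg / (density_g_cm3 * l0_mm)
}

#' Standard phase windows of the twitch and tetanus protocols
#'
#' Frame mid-time windows (ms, relative to the first stimulus) defining the
#' phases used for summary tables: resting (-18.5 to -3.5, four frames),
#' early activation (6.5, one frame), twitch peak force (11.5 and 16.5),
#' twitch mechanical relaxation (81.5-96.5), tetanus peak force (61.5-76.5),
#' tetanus mechanical relaxation (211.5-226.5).
#'
#' @return Named list of `c(lo, hi)` windows (ms, inclusive).
#' @export
phase_windows <- function() {
  list(rest            = c(-18.5, -3.5),
       early_activation = c(6.5, 6.5),
       twitch_PF        = c(11.5, 16.5),
       twitch_relaxed   = c(81.5, 96.5),
       tetanus_PF       = c(61.5, 76.5),
       tetanus_relaxed  = c(211.5, 226.5))
}

#' Phase-window summary of per-frame results
#'
#' Averages per-frame observables over the standard phase windows. With a
#' single series the summary is the within-window mean of each variable;
#' with several series (one per muscle, identified by a `muscle` column)
#' each variable is averaged per muscle first and the mean and SEM across
#' muscles are reported (the per-muscle-first convention; pooled means can
#' differ by ~1% for derived quantities).
#'
#' @param frames data frame with columns `t_ms`, optionally `muscle`, and
#'   one column per observable.
#' @param windows named list of time windows, default [phase_windows()];
#'   windows not covered by the data are dropped with a flag.
#' @return A data frame with columns `phase`, `variable`, `mean`, `sem`,
#'   `n_frames`, `flag`.
#' @export
phase_summary <- function(frames, windows = phase_windows()) {
  stopifnot("t_ms" %in% names(frames))
  has_muscle <- "muscle" %in% names(frames)
  vars <- setdiff(names(frames), c("t_ms", "frame", "muscle"))
  out <- list()
  for (ph in names(windows)) {
    win <- windows[[ph]]
    sel <- frames$t_ms >= win[1] - 1e-9 & frames$t_ms <= win[2] + 1e-9
    if (!any(sel)) {
      out[[length(out) + 1]] <- data.frame(
        phase = ph, variable = vars, mean = NA_real_, sem = NA_real_,
        n_frames = 0L, flag = "missing frames")
      next
    }
    d <- frames[sel, , drop = FALSE]
    for (v in vars) {
      if (has_muscle) {
        per <- tapply(d[[v]], d$muscle, mean, na.rm = TRUE)
        m <- mean(per); s <- stats::sd(per) / sqrt(length(per))
      } else {
        m <- mean(d[[v]], na.rm = TRUE); s <- NA_real_
      }
      out[[length(out) + 1]] <- data.frame(
        phase = ph, variable = v, mean = m, sem = s,
        n_frames = sum(sel), flag = "ok")
    }
  }
  do.call(rbind, out)
}
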