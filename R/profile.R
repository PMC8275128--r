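#' One-dimensional diffracted-intensity profile
#'
#' The basic container used throughout the package: diffracted intensity
#' sampled on a strictly increasing grid of reciprocal spacings, with an
#' optional per-point standard deviation. Grids are treated as point samples
#' (not bins); all reciprocal spacings are in nm^-1 and all real spacings
#' `d = 1/R` in nm.
#'
#' @param R numeric vector of reciprocal spacings (nm^-1), strictly increasing.
#' @param intensity numeric vector of intensities, same length as `R`.
#' @param sd optional numeric vector of per-point standard deviations
#'   (strictly positive where given); `NA` entries are allowed and are treated
#'   as "no uncertainty available" by weighted fits.
#' @return An object of class `"xrd_profile"`: a data frame with columns
#'   `R`, `intensity` and (if supplied) `sd`.
#' @examples
#' p <- xrd_profile(seq(0.066, 0.072, length.out = 30), rexp(30))
#' @export
xrd_profile <- function(R, intensity, sd = NULL) {
  R <- as.numeric(R); intensity <- as.numeric(intensity)
  if (length(R) != length(intensity))
    stop("`R` and `intensity` must have the same length")
  if (anyNA(R) || any(diff(R) <= 0))
    stop("`R` must be strictly increasing and free of NA")
  df <- data.frame(R = R, intensity = intensity)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(R))
      stop("`sd` must have the same length as `R`")
    if (any(sd[!is.na(sd)] <= 0))
      stop("`sd` must be strictly positive where given")
    df$sd <- sd
  }
  class(df) <- c("xrd_profile", "data.frame")
  df
}

#' @export
print.xrd_profile <- function(x, ...) {
  cat(sprintf("<xrd_profile> %d points, R in [%.5g, %.5g] nm^-1\n",
              nrow(x), min(x$R), max(x$R)))
  invisible(x)
}

# TRUE when the two profiles share an identical grid
same_grid <- function(a, b, tol = 1e-12) {
  nrow(a) == nrow(b) && all(abs(a$R - b$R) < tol)
}

# uniform-grid step; errors if the grid is visibly non-uniform
grid_step <- function(R, what = "profile") {
  h <- diff(R)
  if (diff(range(h)) > 1e-8 * mean(h))
    stop(sprintf("%s requires a uniform grid", what))
  mean(h)
}

#' Restrict a profile to an R window
#'
#' @param profile an [xrd_profile()].
#' @param window numeric length-2, `c(lo, hi)` in nm^-1 (inclusive).
#' @return The sub-profile inside the window.
#' @export
profile_window <- function(profile, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- profile$R >= window[1] & profile$R <= window[2]
  if (!any(keep)) stop("window contains no profile points")
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(profile)
  out
}

#' Frame-resolved time series of profiles
#'
#' Bundles an ordered set of per-frame profiles with frame mid-times and the
#' stimulation protocol that produced them. Frame mid-times refer to the
#' centre of each acquisition window.
#'
#' @param profiles list of [xrd_profile()] objects, one per frame.
#' @param t_ms numeric vector of frame mid-times (ms), strictly increasing.
#' @param protocol optional [acquisition_protocol()] describing the recording.
#' @return An object of class `"xrd_series"`.
#' @export
xrd_series <- function(profiles, t_ms, protocol = NULL) {
  if (!is.list(profiles) || !all(vapply(profiles, inherits, TRUE, "xrd_profile")))
    stop("`profiles` must be a list of xrd_profile objects")
  t_ms <- as.numeric(t_ms)
  if (length(t_ms) != length(profiles))
    stop("one frame time per profile required")
  if (any(diff(t_ms) <= 0)) stop("frame mid-times must be strictly increasing")
  structure(list(profiles = profiles, t_ms = t_ms, protocol = protocol),
            class = "xrd_series")
}

#' @export
print.xrd_series <- function(x, ...) {
  cat(sprintf("<xrd_series> %d frames, t = %.1f ... %.1f ms\n",
              length(x$profiles), x$t_ms[1], x$t_ms[length(x$t_ms)]))
  invisible(x)
}

#' Indices of the pre-stimulus (resting) frames of a series
#'
#' The resting reference used for intensity normalisation is the mean over the
#' frames acquired before the first stimulus (four frames in the standard
#' protocols).
#'
#' @param series an [xrd_series()].
#' @return Integer vector of frame indices.
#' @export
resting_frames <- function(series) {
  if (!is.null(series$protocol)) {
    first_stim <- min(series$protocol$stimulus_times)
    idx <- which(series$t_ms < first_stim)
    if (length(idx)) return(idx)
  }
  seq_len(min(4L, length(series$profiles)))
}

#' Read and write tabular profiles
#'
#' Plain-text interchange format: whitespace- or comma-separated columns
#' `R_nm_inv`, `intensity` and optionally `sd`, with a header line.
#'
#' @param file path to a text file.
#' @return [read_profile()] returns an [xrd_profile()].
#' @export
read_profile <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "", comment.char = "#")
  if (ncol(df) == 1) df <- utils::read.csv(file, comment.char = "#")
  need <- c("R_nm_inv", "intensity")
  if (!all(need %in% names(df)))
    stop("profile file must have columns R_nm_inv, intensity[, sd]")
  xrd_profile(df$R_nm_inv, df$intensity, if ("sd" %in% names(df)) df$sd)
}

#' @param profile an [xrd_profile()] to write.
#' @rdname read_profile
#' @export
write_profile <- function(profile, file) {
  out <- data.frame(R_nm_inv = profile$R, intensity = profile$intensity)
  if (!is.null(profile$sd)) out$sd <- profile$sd
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read and write a profile time series in long format
#'
#' Long-format table with columns `frame`, `t_ms`, `R_nm_inv`, `intensity`
#' and optionally `sd`; one row per sample point.
#'
#' @param file path to a text file.
#' @param series an [xrd_series()].
#' @return [read_series()] returns an [xrd_series()] (without protocol
#'   metadata, which the file does not carry).
#' @export
read_series <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "", comment.char = "#")
  frames <- sort(unique(df$frame))
  profs <- lapply(frames, function(f) {
    d <- df[df$frame == f, ]
    d <- d[order(d$R_nm_inv), ]
    xrd_profile(d$R_nm_inv, d$intensity, if ("sd" %in% names(d)) d$sd)
  })
  t_ms <- vapply(frames, function(f) df$t_ms[df$frame == f][1], 0)
  xrd_series(profs, t_ms)
}

#' @rdname read_series
#' @export
write_series <- function(series, file) {
  rows <- lapply(seq_along(series$profiles), function(i) {
    p <- series$profiles[[i]]
    d <- data.frame(frame = i, t_ms = series$t_ms[i],
                    R_nm_inv = p$R, intensity = p$intensity)
    d$sd <- if (!is.null(p$sd)) p$sd else NA_real_
    d
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

# run code with a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
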