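#' Idealised 2D diffraction pattern
#'
#' A small rectangular detector array in reciprocal coordinates, used to
#' exercise the projection stage. Rows index the axial (meridional)
#' coordinate, columns the radial coordinate; the meridian is at radial 0.
#' This is an idealised array: no module gaps, centring or geometry
#' corrections are modelled.
#'
#' @param I numeric matrix of intensities, `length(axial)` x `length(radial)`.
#' @param axial numeric vector of axial reciprocal spacings (nm^-1),
#'   strictly increasing and uniform.
#' @param radial numeric vector of radial reciprocal spacings (nm^-1),
#'   strictly increasing and uniform, spanning both sides of the meridian.
#' @return An object of class `"xrd_pattern2d"`.
#' @export
xrd_pattern2d <- function(I, axial, radial) {
  I <- as.matrix(I)
  if (nrow(I) != length(axial) || ncol(I) != length(radial))
    stop("dimensions of `I` must match `axial` x `radial`")
  grid_step(axial, "xrd_pattern2d (axial)")
  grid_step(radial, "xrd_pattern2d (radial)")
  structure(list(I = I, axial = as.numeric(axial), radial = as.numeric(radial)),
            class = "xrd_pattern2d")
}

#' @export
print.xrd_pattern2d <- function(x, ...) {
  cat(sprintf("<xrd_pattern2d> %d x %d, axial [%.4g, %.4g], radial [%.4g, %.4g] nm^-1\n",
              nrow(x$I), ncol(x$I), min(x$axial), max(x$axial),
              min(x$radial), max(x$radial)))
  invisible(x)
}

#' Generate a toy 2D pattern of mirrored Gaussian blobs
#'
#' Places separable Gaussian blobs on the array, mirrored about both the
#' meridional and equatorial axes as in a centred fibre pattern. Each placed
#' blob integrates (sum x pixel area) to its stated intensity; a reflection
#' away from an axis therefore contributes one blob of that intensity per
#' mirror position.
#'
#' @param reflections data frame with columns `axial_centre`, `radial_centre`
#'   (0 for meridional reflections), `axial_sigma`, `radial_sigma`,
#'   `intensity`.
#' @param axial,radial grid vectors as in [xrd_pattern2d()].
#' @return An [xrd_pattern2d()].
#' @export
generate_pattern2d <- function(reflections, axial, radial) {
  req <- c("axial_centre", "radial_centre", "axial_sigma", "radial_sigma",
           "intensity")
  if (!all(req %in% names(reflections)))
    stop("`reflections` needs columns ", paste(req, collapse = ", "))
  if (any(reflections$axial_sigma <= 0 | reflections$radial_sigma <= 0))
    stop("blob sigmas must be positive")
  if (any(abs(reflections$axial_centre) > max(abs(axial)) |
          abs(reflections$radial_centre) > max(abs(radial))))
    stop("blob centres must lie within the array bounds")
  ha <- grid_step(axial, "generate_pattern2d (axial)")
  hr <- grid_step(radial, "generate_pattern2d (radial)")
  I <- matrix(0, length(axial), length(radial))
  for (i in seq_len(nrow(reflections))) {
    r <- reflections[i, ]
    centres <- unique(expand.grid(a = c(r$axial_centre, -r$axial_centre),
                                  x = c(r$radial_centre, -r$radial_centre)))
    for (j in seq_len(nrow(centres))) {
      ga <- stats::dnorm(axial, centres$a[j], r$axial_sigma)
      gr <- stats::dnorm(radial, centres$x[j], r$radial_sigma)
      I <- I + r$intensity * outer(ga, gr)  # densities: sum * ha * hr ~ 1
    }
  }
  xrd_pattern2d(I, axial, radial)
}

#' Meridional projection of a 2D pattern
#'
#' Integrates the pattern across the meridian, summing the radial band
#' `|radial| <= halfwidth` (times the radial pixel width) at each axial
#' sample. The axial grid is preserved.
#'
#' @param pattern an [xrd_pattern2d()].
#' @param halfwidth radial half-width of the integration band (nm^-1);
#'   defaults to the standard meridional window.
#' @return An [xrd_profile()] on the axial grid.
#' @export
project_meridional <- function(pattern,
                               halfwidth = xrd_windows()$meridian_halfwidth) {
  if (halfwidth <= 0) stop("`halfwidth` must be positive")
  if (halfwidth > max(abs(pattern$radial)) + 1e-12)
    stop("`halfwidth` exceeds the radial extent of the pattern")
  hr <- grid_step(pattern$radial, "project_meridional")
  band <- abs(pattern$radial) <= halfwidth + 1e-12
  xrd_profile(pattern$axial, rowSums(pattern$I[, band, drop = FALSE]) * hr)
}

#' Cross-meridional width of a reflection
#'
#' Integrates the pattern over an axial range and fits a single Gaussian
#' centred on the meridian to the resulting radial distribution; the fitted
#' sigma is the cross-meridional width used to correct meridional
#' intensities for lateral filament misalignment.
#'
#' @param pattern an [xrd_pattern2d()].
#' @param axial_range numeric length-2 axial window (nm^-1).
#' @return A list with `sigma` (nm^-1), `amplitude`, `converged` flag and the
#'   fitted radial profile.
#' @export
cross_meridional_width <- function(pattern, axial_range) {
  rows <- pattern$axial >= axial_range[1] & pattern$axial <= axial_range[2]
  if (!any(rows)) stop("`axial_range` lies outside the pattern")
  y <- colSums(pattern$I[rows, , drop = FALSE])
  x <- pattern$radial
  # moment-based start, then least squares for (amplitude, sigma)
  w0 <- sqrt(max(sum(y * x^2) / sum(y), grid_step(x)^2))
  fit <- minpack.lm::nls.lm(
    par = c(logA = log(max(y)), logs = log(w0)),
    fn = function(p) y - exp(p[["logA"]]) * exp(-x^2 / (2 * exp(2 * p[["logs"]]))),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  list(sigma = exp(fit$par[["logs"]]),
       amplitude = exp(fit$par[["logA"]]),
       converged = fit$info %in% 1:4,
       radial_profile = data.frame(radial = x, intensity = y))
}
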