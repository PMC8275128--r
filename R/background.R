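#' Convex-hull background subtraction
#'
#' Estimates the smooth diffuse background under a profile as the lower
#' convex hull of the `(R, intensity)` point set, anchored at the window
#' endpoints and evaluated between hull vertices by linear interpolation.
#' The corrected profile is exactly zero at the hull vertices and
#' non-negative nowhere below zero at any sample, so the operation is
#' idempotent.
#'
#' @param profile an [xrd_profile()] with at least 3 points.
#' @return A list with components `background` and `corrected`, both
#'   [xrd_profile()] objects on the input grid. Per-point `sd`, if present,
#'   is carried over unchanged to `corrected`.
#' @examples
#' p <- xrd_profile(1:10, 2 * (1:10) + 5)   # straight line
#' range(convex_hull_background(p)$corrected$intensity)  # all ~0
#' @export
convex_hull_background <- function(profile) {
  n <- nrow(profile)
  if (n < 3) stop("convex-hull background needs at least 3 points")
  bg <- lower_hull_interp(profile$R, profile$intensity)
  corrected <- xrd_profile(profile$R, profile$intensity - bg, profile$sd)
  list(background = xrd_profile(profile$R, bg),
       corrected = corrected)
}

# lower convex hull by Andrew's monotone chain (x already sorted increasing),
# evaluated at every x by linear interpolation between hull vertices
lower_hull_interp <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      j <- hull[length(hull)]; k <- hull[length(hull) - 1]
      # pop j if it lies on or above the chord k -> i
      if ((x[j] - x[k]) * (y[i] - y[k]) <= (y[j] - y[k]) * (x[i] - x[k]))
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  stats::approx(x[hull], y[hull], xout = x, method = "linear")$y
}

#' Residual background removal from a reference region
#'
#' After convex-hull subtraction a small residual background can remain; it
#' is removed by subtracting, point by point, the intensity distribution
#' observed in a nearby region of the pattern containing no reflections.
#'
#' @param profile an [xrd_profile()].
#' @param reference an [xrd_profile()] on the same grid.
#' @return The corrected [xrd_profile()].
#' @export
subtract_residual_background <- function(profile, reference) {
  if (!same_grid(profile, reference))
    stop("reference profile must be on the same R grid")
  xrd_profile(profile$R, profile$intensity - reference$intensity, profile$sd)
}
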