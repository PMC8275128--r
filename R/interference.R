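#' Thick-filament interference model of the M3 reflection
#'
#' Structural forward model of the axial profile of the M3 meridional
#' reflection. Each half of the bipolar thick filament carries 49 layers of
#' myosin motors with axial periodicity `d` (nm), the first layer a distance
#' `hbz` (half-bare zone, nm) from the filament midpoint. Only the layers
#' from `n_m` to `n_d` are axially ordered and diffract; each ordered layer
#' is represented as a point diffractor. The two mirror-symmetric arrays
#' interfere, producing fine sub-peak structure with fringe period `1/D`
#' where `D = 2*hbz + (n_m + n_d - 2)*d` is the distance between the array
#' centres.
#'
#' @param hbz half-bare zone (nm).
#' @param d axial periodicity between adjacent motor layers (nm).
#' @param n_m,n_d integer indices of the first and last ordered layer,
#'   `1 <= n_m <= n_d <= n_layers`.
#' @param y intensity scaling factor (>= 0).
#' @param n_layers layers of motors per half-filament (49 in vertebrate
#'   thick filaments).
#' @return An object of class `"tf_model"` with the fields above plus the
#'   derived number of ordered layers `N = n_d - n_m + 1` and interference
#'   distance `D`.
#' @examples
#' m <- tf_model(hbz = 90.58, d = 14.552, n_m = 1, n_d = 49)
#' m$D   # interference distance, nm
#' @export
tf_model <- function(hbz, d, n_m, n_d, y = 1, n_layers = 49L) {
  n_m <- as.integer(round(n_m)); n_d <- as.integer(round(n_d))
  if (n_m < 1 || n_d < n_m || n_d > n_layers)
    stop("need 1 <= n_m <= n_d <= ", n_layers)
  if (d <= 0 || hbz <= 0) stop("`d` and `hbz` must be positive")
  if (y < 0) stop("`y` must be non-negative")
  structure(list(hbz = hbz, d = d, n_m = n_m, n_d = n_d, y = y,
                 n_layers = as.integer(n_layers),
                 N = n_d - n_m + 1L,
                 D = 2 * hbz + (n_m + n_d - 2) * d),
            class = "tf_model")
}

#' @export
print.tf_model <- function(x, ...) {
  cat(sprintf(
    "<tf_model> hbz = %.2f nm, d = %.4f nm, n_m = %d, n_d = %d (N = %d), y = %.3g, D = %.2f nm\n",
    x$hbz, x$d, x$n_m, x$n_d, x$N, x$y, x$D))
  invisible(x)
}

#' Interference distance of a thick-filament model
#'
#' `D = 2*hbz + (n_m + n_d - 2)*d`, the centre-to-centre distance of the two
#' ordered diffracting arrays; the interference fringes that split the M3
#' reflection have reciprocal period exactly `1/D`.
#'
#' @param model a [tf_model()].
#' @return D in nm.
#' @export
interference_distance <- function(model) {
  2 * model$hbz + (model$n_m + model$n_d - 2) * model$d
}

# N-slit grating factor [sin(N pi R d)/sin(pi R d)]^2 with its limit N^2 at
# the zeros of the denominator
slit_factor <- function(R, N, d) {
  den <- sin(pi * R * d)
  out <- numeric(length(R))
  small <- abs(den) < 1e-9
  out[!small] <- (sin(N * pi * R[!small] * d) / den[!small])^2
  out[small] <- N^2
  out
}

#' Unscaled model intensity of the M3 reflection
#'
#' Evaluates `I(R) = [sin(N pi R d)/sin(pi R d)]^2 * [cos(pi R D)]^2`, the
#' product of the N-slit factor of one ordered array and the two-array
#' interference factor. At reciprocal spacings where `sin(pi R d) = 0` the
#' N-slit factor takes its limiting value `N^2`. The model's intensity
#' scaling factor `y` is *not* applied here.
#'
#' @param R reciprocal spacing(s), nm^-1, > 0.
#' @param model a [tf_model()].
#' @return Numeric vector of non-negative intensities.
#' @export
interference_intensity <- function(R, model) {
  if (any(R <= 0)) stop("`R` must be positive")
  slit_factor(R, model$N, model$d) * cos(pi * R * model$D)^2
}

#' Gaussian point-spread convolution of a profile
#'
#' Discrete convolution with a Gaussian kernel of the given sigma on a
#' uniform grid, with reflection padding at the edges; kernel rows are
#' normalised so the integral is conserved.
#'
#' @param profile an [xrd_profile()] on a uniform grid.
#' @param sigma point-spread sigma in nm^-1 (see [psf_sigma_reciprocal()]).
#' @return The convolved [xrd_profile()] (sd, if any, is dropped).
#' @export
convolve_psf <- function(profile, sigma) {
  R <- profile$R
  h <- grid_step(R, "convolve_psf")
  if (sigma < h * 1e-6) return(xrd_profile(R, profile$intensity))
  pad <- ceiling(4 * sigma / h)
  y <- profile$intensity
  yext <- c(rev(y[seq_len(pad) + 1L]), y, rev(y[length(y) - seq_len(pad)]))
  k <- stats::dnorm(seq(-pad, pad) * h, 0, sigma)
  k <- k / sum(k)
  out <- as.numeric(stats::filter(yext, k, sides = 2))[pad + seq_along(y)]
  xrd_profile(R, out)
}

# Gaussian smoothing matrix mapping an extended uniform grid onto the fit
# window; rows normalised to sum 1. Used by the forward model so that the
# generator and the fitter apply bit-identical convolution.
psf_kernel <- function(R, sigma) {
  h <- grid_step(R, "psf kernel")
  if (sigma < h * 1e-6) {
    return(list(Rext = R, K = diag(length(R))))
  }
  pad <- ceiling(4 * sigma / h)
  Rext <- R[1] + (seq_len(length(R) + 2 * pad) - pad - 1) * h
  K <- outer(R, Rext, function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
  list(Rext = Rext, K = K / rowSums(K))
}

# forward model on a uniform window grid: model intensity evaluated on the
# PSF-padded grid, convolved, cropped, scaled by y
m3_forward <- function(R, model, psf_sigma) {
  ker <- psf_kernel(R, psf_sigma)
  as.numeric(model$y * (ker$K %*% interference_intensity(ker$Rext, model)))
}

#' Search-space settings for [fit_m3_model()]
#'
#' @param hbz,d continuous search bounds (nm).
#' @param n_layers maximum layer index (49).
#' @param d_step,D_step coarse grid steps (nm) of the first search stage in
#'   the axial periodicity and the interference distance.
#' @param n_refine how many of the best array lengths `N` to refine.
#' @param n_starts local-optimisation starts per refined `N`.
#' @return A list of settings.
#' @export
m3_search <- function(hbz = c(70, 100), d = c(14, 15), n_layers = 49L,
                      d_step = 0.05, D_step = 1.0,
                      n_refine = 8L, n_starts = 10L) {
  stopifnot(hbz[1] < hbz[2], d[1] < d[2], n_layers >= 1)
  list(hbz = hbz, d = d, n_layers = as.integer(n_layers),
       d_step = d_step, D_step = D_step,
       n_refine = as.integer(n_refine), n_starts = as.integer(n_starts))
}

#' Global chi-square fit of the M3 interference model
#'
#' Fits the thick-filament interference model to an observed M3 axial
#' profile by a global search over the integer layer indices and the
#' continuous parameters. The model intensity depends on the integers only
#' through the array length `N = n_d - n_m + 1` and the interference
#' distance `D`, so the search runs over `(N, d, D)`: an exhaustive coarse
#' grid (every admissible `N`, `d` and `D` on the configured steps) followed
#' by bounded local optimisation of `(d, D)` from the best starting points.
#' The intensity scale `y` enters linearly and is profiled out in closed
#' form at every step, using weights `1/sd^2` when per-point standard
#' deviations are present. The procedure is deterministic for fixed grids.
#'
#' Solutions `(n_m, n_d, hbz)` and `(n_m + k, n_d + k, hbz - k*d)` produce
#' identical model intensities; all members of this degenerate set that
#' respect the layer and `hbz` bounds are reported, and the primary solution
#' is the member whose `hbz` is closest to the centre of the `hbz` search
#' interval (the anatomical half-bare zone is ~80 nm).
#'
#' @param observed an [xrd_profile()] covering the fit window, ideally with
#'   per-point standard deviations.
#' @param psf_sigma point-spread sigma in nm^-1.
#' @param search a [m3_search()] settings list.
#' @param window axial fit window, default the M3 window.
#' @return An object of class `"m3_fit"`: `model` (the primary [tf_model()]),
#'   `chi2`, `reduced_chi2`, `degenerate` (data frame of equivalent
#'   `n_m`, `n_d`, `hbz`), `fitted` profile, `window`, `n_points`.
#' @export
fit_m3_model <- function(observed, psf_sigma = psf_sigma_reciprocal(),
                         search = m3_search(),
                         window = xrd_windows()$m3_axial) {
  sub <- profile_window(observed, window)
  R <- sub$R
  if (length(R) < 10) stop("fit window contains too few points")
  grid_step(R, "fit_m3_model")
  y_obs <- sub$intensity
  if (!is.null(sub$sd)) {
    if (all(!is.na(sub$sd)) && all(sub$sd == 0))
      stop("all-zero standard deviations: weights undefined")
    w <- fit_weights(sub)
  } else w <- rep(1, length(R))

  ker <- psf_kernel(R, psf_sigma)
  Rext <- ker$Rext; K <- ker$K
  sytot <- sum(w * y_obs^2)
  nl <- search$n_layers

  # chi^2 with y profiled out, for a model matrix whose columns are
  # candidate convolved intensities
  chi2_cols <- function(M) {
    num <- colSums(w * y_obs * M)
    den <- colSums(w * M^2)
    ch <- sytot - ifelse(num > 0, num^2 / pmax(den, 1e-300), 0)
    pmax(ch, 0)
  }

  d_grid <- seq(search$d[1], search$d[2], by = search$d_step)
  starts <- vector("list", nl)
  for (N in seq_len(nl)) {
    cand <- NULL
    for (d in d_grid) {
      slit <- slit_factor(Rext, N, d)
      D_lo <- 2 * search$hbz[1] + (N - 1) * d
      D_hi <- 2 * search$hbz[2] + (2 * nl - N - 1) * d
      D <- seq(D_lo, D_hi, by = search$D_step)
      M <- K %*% (slit * cos(pi * outer(Rext, D))^2)
      ch <- chi2_cols(M)
      # local minima along D (plus the end points)
      loc <- which(diff(sign(diff(ch))) > 0) + 1L
      loc <- unique(c(1L, loc, length(ch)))
      cand <- rbind(cand, data.frame(d = d, D = D[loc], chi2 = ch[loc]))
    }
    cand <- cand[order(cand$chi2), ]
    # de-duplicate starts that sit in the same interference-fringe basin
    # (adjacent basins are aliases D +- ~1/R; chi^2 separates them only
    # after refinement, so refine one start per distinct D)
    keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (length(keep) >= search$n_starts) break
      if (!length(keep) || all(abs(cand$D[i] - cand$D[keep]) > 5))
        keep <- c(keep, i)
    }
    starts[[N]] <- cbind(N = N, cand[keep, , drop = FALSE])
  }

  best_by_N <- vapply(starts, function(s) min(s$chi2), 0)
  refine_N <- order(best_by_N)[seq_len(min(search$n_refine, nl))]

  # single-candidate chi^2, computed from residuals (no cancellation)
  obj <- function(p, N) {
    slit <- slit_factor(Rext, N, p[1])
    m <- as.numeric(K %*% (slit * cos(pi * Rext * p[2])^2))
    num <- sum(w * y_obs * m)
    yh <- if (num > 0) num / sum(w * m^2) else 0
    sum(w * (y_obs - yh * m)^2)
  }
  cands <- list()
  for (N in refine_N) {
    st <- starts[[N]]
    for (i in seq_len(nrow(st))) {
      opt <- stats::nlminb(
        start = c(st$d[i], st$D[i]), objective = obj, N = N,
        lower = c(search$d[1], 2 * search$hbz[1] + (N - 1) * search$d[1]),
        upper = c(search$d[2], 2 * search$hbz[2] + (2 * nl - N - 1) * search$d[2]),
        control = list(rel.tol = 1e-14, abs.tol = 0, iter.max = 400))
      deg <- degenerate_set(N, opt$par[1], opt$par[2], search$hbz, nl)
      if (nrow(deg) == 0) next
      cands[[length(cands) + 1]] <-
        data.frame(N = N, d = opt$par[1], D = opt$par[2], chi2 = opt$objective)
    }
  }
  if (!length(cands)) stop("empty search space: no admissible solution")
  cands <- do.call(rbind, cands)
  cands <- cands[order(cands$chi2, abs(cands$N - 45)), ]

  # polish the leading candidates by nested 1D minimisation: the chi^2
  # valley in (d, D) is steep and badly scaled, where quasi-Newton steps
  # can stall short of the minimum
  n_pol <- min(8L, nrow(cands))
  for (i in seq_len(n_pol)) {
    N <- cands$N[i]
    inner <- function(d) stats::optimize(function(D) obj(c(d, D), N),
                                         interval = cands$D[i] + c(-8, 8),
                                         tol = 1e-9)
    od <- stats::optimize(function(d) inner(d)$objective,
                          interval = pmin(pmax(cands$d[i] + c(-0.04, 0.04),
                                               search$d[1]), search$d[2]),
                          tol = 1e-10)
    oD <- inner(od$minimum)
    if (oD$objective < cands$chi2[i] &&
        nrow(degenerate_set(N, od$minimum, oD$minimum, search$hbz, nl)) > 0) {
      cands$d[i] <- od$minimum; cands$D[i] <- oD$minimum
      cands$chi2[i] <- oD$objective
    }
  }
  cands <- cands[order(cands$chi2, abs(cands$N - 45)), ]
  top <- cands[1, ]

  deg <- degenerate_set(top$N, top$d, top$D, search$hbz, nl)
  primary <- deg[which.min(abs(deg$hbz - mean(search$hbz))), ]

  # closed-form scale at the optimum
  slit <- slit_factor(Rext, top$N, top$d)
  m <- as.numeric(K %*% (slit * cos(pi * Rext * top$D)^2))
  yscale <- max(0, sum(w * y_obs * m) / sum(w * m^2))
  model <- tf_model(primary$hbz, top$d, primary$n_m, primary$n_d,
                    y = yscale, n_layers = nl)
  npt <- length(R)
  top$chi2 <- sum(w * (y_obs - yscale * m)^2)
  structure(list(model = model,
                 chi2 = top$chi2,
                 reduced_chi2 = top$chi2 / max(npt - 5, 1),
                 degenerate = deg,
                 fitted = xrd_profile(R, yscale * m),
                 window = window, n_points = npt,
                 candidates = utils::head(cands, 10)),
            class = "m3_fit")
}

# all (n_m, n_d, hbz) triples consistent with a given (N, d, D) and the
# layer/hbz bounds; exact model-intensity degeneracy class
degenerate_set <- function(N, d, D, hbz_bounds, n_layers, tol = 1e-6) {
  n_m <- seq_len(n_layers - N + 1)
  hbz <- (D - (2 * n_m + N - 3) * d) / 2
  ok <- hbz >= hbz_bounds[1] - tol & hbz <= hbz_bounds[2] + tol
  data.frame(n_m = n_m[ok], n_d = n_m[ok] + N - 1, hbz = hbz[ok])
}

#' @export
print.m3_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  chi2 = %.4g (reduced %.4g), %d points in [%.3f, %.3f] nm^-1\n",
              x$chi2, x$reduced_chi2, x$n_points, x$window[1], x$window[2]))
  if (nrow(x$degenerate) > 1)
    cat(sprintf("  %d degenerate (n_m, n_d, hbz) solutions (equal N, D)\n",
                nrow(x$degenerate)))
  invisible(x)
}
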