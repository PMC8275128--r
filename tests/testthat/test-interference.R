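test_that("model container derives N and D and enforces layer bounds", {
  m <- tf_model(79.51, 14.348, 2, 46)
  expect_equal(m$N, 45L)
  expect_equal(m$D, 2 * 79.51 + 46 * 14.348)
  expect_error(tf_model(80, 14.4, 0, 46), "n_m")
  expect_error(tf_model(80, 14.4, 5, 50), "n_m")
  expect_equal(interference_distance(tf_model(80, 14.4, 1, 1)), 160)
  expect_equal(interference_distance(tf_model(79.51, 14.348, 2, 46)),
               819.028, tolerance = 1e-6)
  expect_equal(interference_distance(tf_model(90.58, 14.552, 1, 49)),
               879.656, tolerance = 1e-6)
})

test_that("single-layer arrays reduce to the pure interference factor", {
  m <- tf_model(80, 14.4, 3, 3)     # N = 1
  R <- seq(0.066, 0.072, length.out = 50)
  expect_equal(interference_intensity(R, m), cos(pi * R * m$D)^2,
               tolerance = 1e-12)
})

test_that("the N-slit factor takes its limit N^2 at the principal maximum", {
  m <- tf_model(80, 14.4, 1, 49)
  R0 <- 1 / m$d
  expect_equal(interference_intensity(R0, m) / cos(pi * R0 * m$D)^2, 49^2)
  # continuous approach to the limit
  eps <- 1e-10
  expect_equal(interference_intensity(R0 + eps, m),
               interference_intensity(R0, m), tolerance = 1e-4)
})

test_that("interference fringes have reciprocal period exactly 1/D", {
  D <- 909
  R <- seq(0.0655, 0.0725, by = 1e-7)
  f <- cos(pi * R * D)^2
  pk <- which(diff(sign(diff(f))) < 0) + 1
  gaps <- diff(R[pk])
  expect_equal(mean(gaps), 1 / D, tolerance = 1e-4)
  expect_equal(round(1 / D, 4), 0.0011)   # the observed M6 sub-peak separation
})

test_that("PSF convolution conserves mass and behaves in its limits", {
  R <- seq(0.066, 0.072, length.out = 121)
  h <- R[2] - R[1]
  y <- 2 * dnorm(R, 0.0687, 3e-4) + 1
  p <- xrd_profile(R, y)
  expect_equal(convolve_psf(p, 0)$intensity, y, tolerance = 1e-9)
  sig <- 2.3e-4
  conv <- convolve_psf(p, sig)
  expect_lt(abs(sum(conv$intensity) - sum(y)) / sum(y), 0.001)
  # delta-like input spreads to a Gaussian of the kernel width
  d0 <- numeric(121); d0[61] <- 1
  dd <- convolve_psf(xrd_profile(R, d0), sig)
  expect_equal(dd$intensity / sum(dd$intensity) / h,
               dnorm(R, R[61], sig), tolerance = 0.02)
  # two peaks: separation unchanged, valley raised
  y2 <- dnorm(R, 0.068, 2e-4) + dnorm(R, 0.070, 2e-4)
  c2 <- convolve_psf(xrd_profile(R, y2), sig)
  pk <- which(diff(sign(diff(c2$intensity))) < 0) + 1
  expect_equal(R[pk], c(0.068, 0.0700), tolerance = h)
  valley <- function(v) min(v[R > 0.0685 & R < 0.0695])
  expect_gt(valley(c2$intensity), valley(y2))
  expect_error(convolve_psf(xrd_profile(R^2, y), sig), "uniform grid")
})

test_that("noiseless forward profiles refit to the generating parameters", {
  rows <- tf_phase_models()
  for (i in c(1, 5)) {       # rest and tetanus-PF phases
    truth <- tf_model(rows$hbz[i], rows$d[i], rows$n_m[i], rows$n_d[i],
                      y = rows$y[i])
    fit <- fit_m3_model(generate_m3_profile(truth))
    expect_equal(fit$model$n_m, truth$n_m)
    expect_equal(fit$model$n_d, truth$n_d)
    expect_lt(abs(fit$model$hbz - truth$hbz) / truth$hbz, 1e-6)
    expect_lt(abs(fit$model$d - truth$d) / truth$d, 1e-6)
    expect_equal(fit$model$y, truth$y, tolerance = 1e-4)
  }
})

test_that("scaling the observed profile only rescales the intensity factor", {
  truth <- tf_model(90.58, 14.552, 1, 49, y = 2)
  p <- generate_m3_profile(truth, noise_fraction = 0.01, seed = 3)
  k <- 7.5
  p2 <- xrd_profile(p$R, k * p$intensity, sd = k * p$sd)
  f1 <- fit_m3_model(p)
  f2 <- fit_m3_model(p2)
  expect_equal(f2$model$hbz, f1$model$hbz, tolerance = 1e-6)
  expect_equal(f2$model$d, f1$model$d, tolerance = 1e-8)
  expect_equal(f2$model$n_m, f1$model$n_m)
  expect_equal(f2$model$y, k * f1$model$y, tolerance = 1e-5)
})

test_that("exactly degenerate layer assignments are detected and reported", {
  # (n_m, n_d, hbz) and (n_m+k, n_d+k, hbz-k*d) give identical intensities
  truth <- tf_model(79.51, 14.348, 2, 46, y = 4.5)
  twin <- tf_model(79.51 + 14.348, 14.348, 1, 45, y = 4.5)
  R <- seq(0.066, 0.072, length.out = 30)
  expect_equal(interference_intensity(R, truth),
               interference_intensity(R, twin), tolerance = 1e-12)
  fit <- fit_m3_model(generate_m3_profile(truth))
  expect_equal(nrow(fit$degenerate), 2)
  expect_setequal(fit$degenerate$n_m, c(1, 2))
  hbzs <- sort(fit$degenerate$hbz)
  expect_equal(diff(hbzs), fit$model$d, tolerance = 1e-4)
  # primary solution is the anatomically plausible member
  expect_equal(fit$model$n_m, 2L)
  expect_equal(fit$model$hbz, 79.51, tolerance = 1e-4)
})

test_that("the fitted chi-square never exceeds that of the generating model", {
  truth <- tf_model(85.65, 14.416, 9, 43, y = 5.1)
  p <- generate_m3_profile(truth, noise_fraction = 0.01, seed = 11)
  fit <- fit_m3_model(p)
  # chi2 of the generating model under the same weights
  m <- generate_m3_profile(truth)$intensity
  chi2_truth <- sum(((p$intensity - m) / p$sd)^2)
  expect_lte(fit$chi2, chi2_truth * (1 + 1e-9))
})

test_that("the global search agrees with a dense brute-force oracle", {
  # oracle: direct evaluation of the interference formula (written out
  # independently) on a dense five-parameter lattice, no PSF
  oracle <- function(p, n_m_range, n_d_range, hbz_grid, d_grid) {
    R <- p$R; y <- p$intensity
    best <- list(chi2 = Inf)
    for (n_m in n_m_range) for (n_d in n_d_range) {
      if (n_d < n_m) next
      N <- n_d - n_m + 1
      for (d in d_grid) {
        sl <- (sin(N * pi * R * d) / sin(pi * R * d))^2
        sl[!is.finite(sl)] <- N^2
        for (hbz in hbz_grid) {
          D <- 2 * hbz + (n_m + n_d - 2) * d
          mm <- sl * cos(pi * R * D)^2
          a <- sum(mm * y) / sum(mm^2)
          chi2 <- sum((y - a * mm)^2)
          if (chi2 < best$chi2)
            best <- list(chi2 = chi2, N = N, d = d, D = D)
        }
      }
    }
    best
  }
  rows <- tf_phase_models()
  for (i in c(2, 5, 6)) {
    truth <- tf_model(rows$hbz[i], rows$d[i], rows$n_m[i], rows$n_d[i],
                      y = rows$y[i])
    p <- generate_m3_profile(truth, psf_sigma = 0)
    fit <- fit_m3_model(p, psf_sigma = 0)
    orc <- oracle(p, max(1, truth$n_m - 1):(truth$n_m + 1),
                  (truth$n_d - 1):min(49, truth$n_d + 1),
                  seq(truth$hbz - 2, truth$hbz + 2, by = 0.1),
                  seq(truth$d - 0.05, truth$d + 0.05, by = 0.005))
    expect_lte(fit$chi2, orc$chi2 + 1e-4)   # both ~0; allow float dust
    expect_equal(fit$model$N, orc$N)
    expect_lt(abs(fit$model$d - orc$d), 0.005)
    expect_lt(abs(fit$model$D - orc$D), 0.2 + 0.005 * 96)
  }
})
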