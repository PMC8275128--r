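test_that("global deconvolution recovers time-invariant spacings from a noisy series", {
  prot <- acquisition_protocol("tetanus")
  ml1 <- signal_kinetics(1, 0.09, 8.6, 141.8)
  al1 <- signal_kinetics(1, 2.66, 15.3, 123.4)
  g <- generate_layerline_series(prot, ml1, al1, noise_sd = 0.02, seed = 21)
  dec <- deconvolve_layerlines_global(g$series)
  expect_true(dec$converged)
  expect_equal(dec$s_ml1, 43.0, tolerance = 0.1 / 43)
  expect_equal(dec$s_al1, 36.6, tolerance = 0.1 / 36.6)
  expect_true(dec$al1_identifiable)
  # amplitude/intensity link holds frame by frame
  expect_equal(dec$frames$a_ml1, sqrt(pmax(dec$frames$i_ml1_norm, 0)),
               tolerance = 1e-12)
})

test_that("an absent actin layer line triggers the fixed-spacing fallback", {
  prot <- acquisition_protocol("twitch")
  ml1 <- signal_kinetics(1, 0.28, 8, 29.4)
  none <- signal_kinetics(0, 0, 10, 30)
  g <- generate_layerline_series(prot, ml1, none, noise_sd = 0.01, seed = 4)
  dec <- deconvolve_layerlines_global(g$series)
  expect_false(dec$al1_identifiable)
  fixed <- deconvolve_layerlines_global(g$series, fix_s_al1 = 36.6)
  expect_true(fixed$al1_fixed)
  expect_equal(fixed$s_al1, 36.6)
  expect_lt(mean(fixed$frames$i_al1), 0.05 * mean(fixed$frames$i_ml1))
})

test_that("deconvolution is invariant to frame order and replication", {
  prot <- acquisition_protocol("tetanus")
  ml1 <- signal_kinetics(1, 0.09, 8.6, 141.8)
  al1 <- signal_kinetics(1, 2.66, 15.3, 123.4)
  g <- generate_layerline_series(prot, ml1, al1, noise_sd = 0.02, seed = 8)
  dec <- deconvolve_layerlines_global(g$series)
  perm <- rev(seq_along(g$series$profiles))
  shuffled <- xrd_series(g$series$profiles[perm], g$series$t_ms)
  dec2 <- deconvolve_layerlines_global(shuffled,
                                       resting = which(perm %in% 1:4))
  expect_equal(dec2$s_ml1, dec$s_ml1, tolerance = 1e-7)
  expect_equal(dec2$s_al1, dec$s_al1, tolerance = 1e-7)

  # one frame replicated equals the plain two-Gaussian single-frame fit
  one <- g$series$profiles[[10]]
  rep3 <- xrd_series(list(one, one, one), c(0, 5, 10))
  decr <- deconvolve_layerlines_global(rep3, resting = 1:3)
  single <- fit_gaussians(one, 2, shared_width = TRUE,
                          centres = c(1 / 43, 1 / 36.6))
  expect_equal(sort(c(decr$s_ml1, decr$s_al1)),
               sort(1 / single$components$centre), tolerance = 1e-3)
  expect_error(deconvolve_layerlines_global(
    xrd_series(list(one), 0)), "at least 2 frames")
})

test_that("constrained equatorial fits recover a rest-like lattice", {
  R <- seq(0.02, 0.065, length.out = 220)
  d10 <- 35.32
  p <- gauss_profile(R, c(1, 1.46, sqrt(3), 2) / d10,
                     c(6e-4, 8e-4, 9e-4, 7e-4), c(1.0, 0.15, 0.41, 0.12))
  eq <- fit_equator(p)
  expect_true(eq$converged)
  expect_equal(eq$d_10, 35.32, tolerance = 0.05 / 35.32)
  expect_equal(eq$ratio_11_10, 0.41, tolerance = 0.02 / 0.41)
  # centre constraint identities hold exactly in the result
  expect_equal(eq$centres[3], sqrt(3) * eq$centres[1], tolerance = 1e-12)
  expect_equal(eq$centres[4], 2 * eq$centres[1], tolerance = 1e-12)
  expect_error(fit_equator(p, z_constant = 0.9), "> 1")
})

test_that("equatorial fits respond correctly to intensity and lattice changes", {
  R <- seq(0.02, 0.065, length.out = 220)
  d10 <- 35.0
  equal_int <- gauss_profile(R, c(1, 1.46, sqrt(3), 2) / d10,
                             rep(7e-4, 4), c(0.8, 0.1, 0.8, 0.1))
  eq <- fit_equator(equal_int, d10_start = 35)
  expect_equal(eq$ratio_11_10, 1, tolerance = 1e-3)

  k <- 1.03   # lattice expansion scales all centres by 1/k
  expanded <- gauss_profile(R, c(1, 1.46, sqrt(3), 2) / (d10 * k),
                            rep(7e-4, 4), c(0.8, 0.1, 0.8, 0.1))
  eq2 <- fit_equator(expanded, d10_start = 35)
  expect_equal(eq2$d_10, d10 * k, tolerance = 1e-3)
  expect_equal(eq2$centres, eq$centres / k, tolerance = 1e-3)
})

test_that("even sarcomere orders are assigned and scale consistently", {
  R <- seq(0.0033, 0.0083, length.out = 500)
  prof_for <- function(sl_um, n) {
    gauss_profile(R, n / (sl_um * 1000), rep(5e-5, length(n)),
                  rep(1, length(n)))
  }
  rest <- assign_sarcomere_orders(prof_for(2.41, seq(10, 18, 2)), 2.4)
  expect_equal(rest$flag, "ok")
  expect_equal(rest$orders, seq(10, 18, 2))
  expect_equal(rest$sl, 2.41, tolerance = 1e-4)
  expect_false(is.na(rest$i_s))

  tet <- assign_sarcomere_orders(prof_for(2.13, seq(8, 16, 2)), 2.2)
  expect_equal(tet$orders, seq(8, 16, 2))
  expect_equal(tet$sl, 2.13, tolerance = 1e-4)

  # scaling all peak positions by c divides SL by c
  sc <- 1.04
  scaled <- gauss_profile(R, sc * seq(10, 18, 2) / 2410, rep(5e-5, 5),
                          rep(1, 5))
  r2 <- assign_sarcomere_orders(scaled, 2.4 / sc)
  expect_equal(r2$sl, 2.41 / sc, tolerance = 1e-4)

  # non-harmonic peaks cannot be assigned
  set.seed(2)
  junk <- gauss_profile(R, sort(runif(4, 0.004, 0.008)), rep(5e-5, 4),
                        rep(1, 4))
  expect_equal(assign_sarcomere_orders(junk, 2.4)$flag, "inhomogeneous")
})
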