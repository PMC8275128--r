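test_that("generators are bit-reproducible for a fixed seed and vary across seeds", {
  m <- tf_model(90.58, 14.552, 1, 49, y = 2)
  a <- generate_m3_profile(m, noise_fraction = 0.01, seed = 42)
  b <- generate_m3_profile(m, noise_fraction = 0.01, seed = 42)
  c <- generate_m3_profile(m, noise_fraction = 0.01, seed = 43)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
  # noiseless output is seed-independent
  expect_identical(generate_m3_profile(m, seed = 1)$intensity,
                   generate_m3_profile(m, seed = 2)$intensity)

  prot <- acquisition_protocol("twitch", seed = 5)
  kin <- list(force = signal_kinetics(0, 68, 9, 24.4, noise_sd = 0.02))
  s1 <- generate_timeseries(prot, kin)
  s2 <- generate_timeseries(prot, kin)
  s3 <- generate_timeseries(prot, kin, seed = 6)
  expect_identical(s1$traces$force, s2$traces$force)
  expect_false(identical(s1$traces$force, s3$traces$force))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(generate_m3_profile(tf_model(80, 14.4, 1, 49),
                                noise_fraction = 0.01, seed = 7))
  expect_identical(runif(1), before)
})

test_that("acquisition protocols have the documented frame structure", {
  tw <- acquisition_protocol("twitch")
  te <- acquisition_protocol("tetanus")
  expect_equal(tw$n_frames, 42L)
  expect_equal(te$n_frames, 68L)
  expect_equal(sum(tw$t_ms < min(tw$stimulus_times)), 4)
  expect_equal(tw$t_ms[1:5], c(-18.5, -13.5, -8.5, -3.5, 1.5))
  expect_true(all(diff(te$t_ms) > 0))
  expect_equal(length(tw$stimulus_times), 1)
  expect_equal(max(te$stimulus_times), 100, tolerance = 1e-9)
  expect_equal(diff(te$stimulus_times)[1], 1000 / 130)
})

test_that("stated per-point sd matches the empirical noise across seeds", {
  m <- tf_model(90.58, 14.552, 1, 49, y = 2)
  nf <- 0.02
  sims <- sapply(1:120, function(s)
    generate_m3_profile(m, noise_fraction = nf, seed = s)$intensity)
  stated <- generate_m3_profile(m, noise_fraction = nf, seed = 1)$sd
  empirical <- apply(sims, 1, sd)
  ratio <- empirical / stated
  expect_lt(abs(median(ratio) - 1), 0.1)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("layer-line generator degenerates correctly at its edge cases", {
  p <- generate_layerline_profile(43.0, 36.6, i_ml1 = 1, i_al1 = 0)
  expect_lt(abs(p$R[which.max(p$intensity)] - 1 / 43.0), 2e-4)
  flat <- generate_layerline_profile(43.0, 36.6, 0, 0, background = c(2, 10))
  expect_equal(flat$intensity, 2 + 10 * flat$R, tolerance = 1e-12)
  expect_error(generate_layerline_profile(43, 43), "non-identifiable")
  expect_error(generate_layerline_profile(43, 36.6, axial_width = -1),
               "positive")
})

test_that("noiseless layer-line series round-trips through the deconvolution", {
  prot <- acquisition_protocol("tetanus")
  kin <- signal_kinetics(1, 1, 10, 200)         # constant equal intensities
  g <- generate_layerline_series(prot, kin, kin, noise_sd = 0)
  dec <- deconvolve_layerlines_global(g$series)
  ratio <- dec$frames$i_al1 / dec$frames$i_ml1
  expect_lt(max(abs(ratio - 1)), 1e-6)
  expect_equal(dec$s_ml1, 43.0, tolerance = 1e-4)
  expect_equal(dec$s_al1, 36.6, tolerance = 1e-4)
})

test_that("noiseless time series reproduce their generative half-times", {
  prot <- acquisition_protocol("tetanus")
  kin <- list(force = signal_kinetics(0, 273, 17, 127.3, noise_sd = 0))
  sim <- generate_timeseries(prot, kin)
  expect_identical(sim$traces$force, sim$truth$force)
  fit <- fit_halftime(sim$traces$t_ms, sim$traces$force, "rise",
                      window = c(-20, 95))
  expect_equal(fit$t_half, 17, tolerance = 0.05)
  fall <- fit_halftime(sim$traces$t_ms, sim$traces$force, "fall",
                       reference_time = 100, window = c(100, 340))
  expect_equal(fall$t_half, 27.3, tolerance = 0.2)
})

test_that("2D blobs integrate to their stated intensity and mirror correctly", {
  ax <- seq(0.05, 0.09, by = 2e-4)
  ra <- seq(-0.03, 0.03, by = 2e-4)
  pat <- generate_pattern2d(
    data.frame(axial_centre = 0.07, radial_centre = 0.008,
               axial_sigma = 5e-4, radial_sigma = 2e-3, intensity = 100),
    ax, ra)
  # mirrored pair: projection equals one-sided times two
  one <- xrd_pattern2d(100 * outer(dnorm(ax, 0.07, 5e-4),
                                   dnorm(ra, 0.008, 2e-3)), ax, ra)
  expect_equal(project_meridional(pat, 0.03)$intensity,
               2 * project_meridional(one, 0.03)$intensity, tolerance = 1e-9)
  expect_error(generate_pattern2d(
    data.frame(axial_centre = 0.07, radial_centre = 0, axial_sigma = -1,
               radial_sigma = 2e-3, intensity = 1), ax, ra), "positive")
  expect_error(generate_pattern2d(
    data.frame(axial_centre = 0.2, radial_centre = 0, axial_sigma = 1e-3,
               radial_sigma = 2e-3, intensity = 1), ax, ra), "bounds")
})

test_that("YAML generator configurations are honoured", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "protocol:",
    "  mode: twitch",
    "  seed: 3",
    "kinetics:",
    "  force:",
    "    baseline: 0",
    "    plateau: 68",
    "    t_half_rise: 9",
    "    t_half_fall: 24.4",
    "    noise_sd: 0.02"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$protocol$mode, "twitch")
  sim <- generate_timeseries(cfg$protocol, cfg$kinetics)
  expect_equal(nrow(sim$traces), 42)
})
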