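# fixtures built in code; all deterministic given explicit seeds

# published best-fit thick-filament parameter sets for the six contraction
# phases (rest, early activation, twitch peak force / relax, tetanus peak
# force / relax), used for round-trip studies
tf_phase_models <- function() {
  data.frame(
    phase = c("rest", "early_activation", "twitch_PF", "twitch_relax",
              "tetanus_PF", "tetanus_relax"),
    hbz = c(79.51, 79.40, 85.65, 79.52, 90.58, 79.61),
    n_m = c(2, 3, 9, 2, 1, 2),
    n_d = c(46, 42, 43, 45, 49, 46),
    d = c(14.348, 14.362, 14.416, 14.348, 14.552, 14.340),
    y = c(4.5, 4.9, 5.1, 4.7, 2.0, 5.5),
    ID = c(814, 776, 881, 790, 874, 822))
}

# multi-Gaussian profile on a grid (areas/centres/sigmas given explicitly)
gauss_profile <- function(R, centres, sigmas, areas, sd = NULL) {
  y <- rowSums(vapply(seq_along(centres),
                      function(j) areas[j] * dnorm(R, centres[j], sigmas[j]),
                      numeric(length(R))))
  xrd_profile(R, y, sd)
}

# rest-like three-sub-peak M3 profile (LA/MA/HA sharing one width)
m3_restlike <- function(width = 4e-4) {
  R <- seq(0.066, 0.072, length.out = 120)
  centres <- c(0.06852, 0.06974, 0.07096)
  areas <- c(0.30, 0.50, 0.20)
  list(profile = gauss_profile(R, centres, rep(width, 3), areas),
       centres = centres, areas = areas, width = width)
}
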