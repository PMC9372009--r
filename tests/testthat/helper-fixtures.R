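# Shared fixtures, all generated in code. Expensive ones are memoised so the
# acceptance tests and unit tests can share a single simulation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# noiseless acquisition: every stochastic error model off
noiseless_config <- function(seed = 1L)
  sim_config(seed = seed, ppm_sigma = 0, ion_cv = 0, intensity_cv = 0,
             noise_floor = 0, bleed_intensity = 0)

# two-point calibration used throughout the unit tests: C10 at 600 s,
# C11 at 672 s (the worked midpoint examples)
two_point_calib <- function() alkane_calibration(c(10, 11), c(600, 672))

# a clean Gaussian EIC with known area
gaussian_eic <- function(area = 20000, rt0 = 60, fwhm = 3, period = 0.2,
                         n = 600, mz = 150, rt_shift = 0) {
  rt <- seq(period, by = period, length.out = n)
  sigma <- fwhm / 2.3548
  y <- area / (sigma * sqrt(2 * pi)) * exp(-(rt - rt0 - rt_shift)^2 / (2 * sigma^2))
  y[y < 1e-6] <- 0
  structure(list(target_mz = mz, mz_delta = 0.05, rt = rt, intensity = y,
                 mz = ifelse(y > 0, mz, NA_real_)),
            class = "eic")
}

# unweighted cosine between a component spectrum and a library entry over the
# union of their ions (independent of the scoring path: plain cosine,
# exact-mass pairing at 50 ppm with no m/z weighting)
plain_cosine <- function(comp, entry) {
  q <- component_spectrum(comp)
  p <- match_ions(q, entry, amt_ppm = 50, min_mz = 0)
  match_factor(p, pwf = 1, intensity_power = 1, mz_power = 0)$forward
}

# noiseless self-match benchmark: 26 evenly spaced compounds, C7-C30 alkanes
selfmatch_benchmark <- function() memo("selfmatch", {
  cfg <- noiseless_config(seed = 101L)
  lib <- simulate_library(26, seed = 101L, richness_range = c(4L, 20L),
                          ri_spacing = "even")
  alk <- simulate_alkane_run(c(7L, 30L), config = cfg)
  sim <- simulate_run(lib, levels = 500, calib = alk$calibration, config = cfg)
  dec <- deconvolve_run(sim$run)
  list(lib = lib, calib = alk$calibration, sim = sim, dec = dec, config = cfg)
})

# the standard synthetic screening benchmark: 80-entry suspect library,
# 26 spiked, matrix background, 2 levels x 5 replicates, fixed seed
standard_benchmark <- function() memo("standard", {
  lib <- simulate_library(80, seed = 11L, richness_range = c(3L, 30L))
  set.seed(42L)
  spiked <- sort(sample(lib_names(lib), 26))
  exp <- make_screening_experiment(lib, spiked = spiked,
                                   levels = c(50, 500), replicates = 5L,
                                   seed = 7L)
  decs <- deconvolve_experiment(exp)
  list(lib = lib, spiked = spiked, exp = exp, decs = decs)
})
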