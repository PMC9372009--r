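test_that("spectrum constructors enforce their invariants", {
  expect_error(profile_spectrum(1, c(100, 100), c(1, 2)), "increasing")
  expect_error(profile_spectrum(1, c(100, 101), c(1, -2)), "non-negative")
  expect_error(centroid_spectrum(1, c(100, 200), c(5, 0)), "positive")
  expect_error(ms_run(list(centroid_spectrum(2, 100, 5),
                           centroid_spectrum(1, 100, 5))), "increasing")
  run <- ms_run(list(centroid_spectrum(1, 100, 5),
                     centroid_spectrum(1.2, 100, 5),
                     centroid_spectrum(1.4, 100, 5)))
  expect_equal(run$scan_period, 0.2)
  expect_identical(run$metadata$mode, "centroid")
})

test_that("centroiding recovers peak positions and splits resolved peaks", {
  # symmetric triangular peak: centroid exactly at the apex
  mz <- 150 + seq(-0.02, 0.02, by = 0.005)
  int <- c(1, 2, 3, 4, 5, 4, 3, 2, 1) * 100
  cs <- centroid_profile(profile_spectrum(10, mz, int))
  expect_equal(length(cs$mz), 1L)
  expect_equal(cs$mz, 150, tolerance = 1e-8)
  expect_equal(cs$intensity, 500)

  # two baseline-separated peaks -> exactly 2 centroids
  mz2 <- c(100 + seq(-0.01, 0.01, by = 0.005), 200 + seq(-0.02, 0.02, by = 0.01))
  int2 <- c(1, 5, 9, 5, 1, 2, 6, 11, 6, 2) * 50
  cs2 <- centroid_profile(profile_spectrum(10, mz2, int2))
  expect_equal(length(cs2$mz), 2L)

  # asymmetric 3-point region: intensity-weighted mean
  # = (99.99*10 + 100.00*100 + 100.01*30) / 140 = 100.0014286 Da
  cs3 <- centroid_profile(profile_spectrum(1, c(99.99, 100.00, 100.01),
                                           c(10, 100, 30)), min_points = 3)
  expect_equal(cs3$mz, sum(c(99.99, 100, 100.01) * c(10, 100, 30)) / 140,
               tolerance = 1e-9)
  expect_equal(cs3$mz, 100.0014286, tolerance = 1e-6)

  # empty input
  cs4 <- centroid_profile(profile_spectrum(1, numeric(0), numeric(0)))
  expect_equal(length(cs4$mz), 0L)
})

test_that("centroiding a noiseless simulated profile recovers planted m/z", {
  cfg <- noiseless_config()
  lib <- simulate_library(4, seed = 3L, richness_range = c(5L, 10L),
                          ri_spacing = "even")
  sim <- simulate_run(lib, levels = 500, config = cfg,
                      rts = c(60, 90, 120, 150), duration = 200)
  crun <- centroid_run(sim$run)
  planted <- sort(unique(unlist(lapply(lib$entries, function(e) e$spectrum$mz))))
  # at each planted compound apex, every planted ion has a centroid within
  # half a profile sampling step (fwhm/6)
  rts <- vapply(crun$scans, function(s) s$rt, numeric(1))
  for (i in seq_along(lib$entries)) {
    s <- crun$scans[[which.min(abs(rts - sim$truth$rt[i]))]]
    for (m in lib$entries[[i]]$spectrum$mz) {
      d <- min(abs(s$mz - m))
      expect_lt(d, (m / 5700) / 6)
    }
  }
})

test_that("EIC extraction clusters traces and conserves total ion current", {
  mk_run <- function(peaksets) {
    scans <- lapply(seq_along(peaksets), function(i) {
      p <- peaksets[[i]]
      centroid_spectrum(i * 0.2, p$mz, p$int)
    })
    ms_run(scans, mz_range = c(40, 1000))
  }
  # constant single m/z -> one EIC with per-scan intensities
  run1 <- mk_run(replicate(6, list(mz = 100, int = 50), simplify = FALSE))
  e1 <- extract_eics(run1)
  expect_equal(length(e1), 1L)
  expect_equal(e1[[1]]$target_mz, 100)
  expect_equal(e1[[1]]$intensity, rep(50, 6))

  # alternating 100.000 / 100.200 with window 0.05 -> two EICs
  run2 <- mk_run(lapply(1:6, function(i)
    list(mz = if (i %% 2) 100.0 else 100.2, int = 10 * i)))
  expect_equal(length(extract_eics(run2, 0.05)), 2L)

  # slow drift 100.000 -> 100.004 stays a single EIC (greedy trace oracle:
  # all pairwise gaps <= 0.004 < 0.05, so one trace is the only outcome)
  drift <- seq(100.000, 100.004, length.out = 10)
  run3 <- mk_run(lapply(1:10, function(i) list(mz = drift[i], int = 100)))
  e3 <- extract_eics(run3, 0.05)
  expect_equal(length(e3), 1L)
  expect_equal(e3[[1]]$target_mz, mean(drift), tolerance = 1e-9)

  # profile run rejected
  prun <- ms_run(list(profile_spectrum(1, c(100, 100.01), c(5, 5))))
  expect_error(extract_eics(prun), "centroid")

  # TIC conservation on a busy simulated run
  cfg <- noiseless_config()
  lib <- simulate_library(5, seed = 9L, richness_range = c(4L, 12L),
                          ri_spacing = "even")
  sim <- simulate_run(lib, levels = 300, config = cfg,
                      rts = seq(60, 180, length.out = 5), duration = 220)
  crun <- centroid_run(sim$run)
  eics <- extract_eics(crun)
  expect_equal(total_ion_current(eics), total_ion_current(crun),
               tolerance = 1e-12)
})

test_that("internal run format round-trips", {
  cfg <- noiseless_config()
  lib <- simulate_library(2, seed = 5L, richness_range = c(3L, 6L))
  sim <- simulate_run(lib, levels = 100, config = cfg, rts = c(30, 50),
                      duration = 80)
  path <- withr::local_tempfile(fileext = ".gcrun")
  write_run(sim$run, path, format = "internal")
  back <- read_run(path, format = "internal")
  expect_equal(length(back$scans), length(sim$run$scans))
  expect_equal(back$metadata$mode, "profile")
  for (i in seq_along(back$scans)) {
    expect_equal(back$scans[[i]]$rt, sim$run$scans[[i]]$rt, tolerance = 1e-9)
    expect_equal(back$scans[[i]]$mz, sim$run$scans[[i]]$mz, tolerance = 1e-6)
    expect_equal(back$scans[[i]]$intensity, sim$run$scans[[i]]$intensity,
                 tolerance = 1e-6)
  }
  # empty run round-trips too
  p2 <- withr::local_tempfile(fileext = ".gcrun")
  write_run(ms_run(list()), p2, format = "internal")
  expect_equal(length(read_run(p2, format = "internal")$scans), 0L)
})

test_that("mzML round-trips through mzR with mode flags preserved", {
  cfg <- noiseless_config()
  lib <- simulate_library(2, seed = 6L, richness_range = c(3L, 6L))
  sim <- simulate_run(lib, levels = 100, config = cfg, rts = c(30, 50),
                      duration = 80)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run(sim$run, path, format = "mzml")
  back <- read_run(path, format = "mzml")
  expect_equal(back$metadata$mode, "profile")
  expect_equal(length(back$scans), length(sim$run$scans))
  nz <- which(vapply(sim$run$scans, function(s) length(s$mz), integer(1)) > 0)
  for (i in nz[seq(1, length(nz), length.out = 5)]) {
    expect_equal(back$scans[[i]]$mz, sim$run$scans[[i]]$mz, tolerance = 1e-6)
    expect_equal(back$scans[[i]]$intensity, sim$run$scans[[i]]$intensity,
                 tolerance = 1e-4)
  }
  # centroided run is flagged centroid on re-read
  crun <- centroid_run(sim$run)
  p2 <- withr::local_tempfile(fileext = ".mzML")
  write_run(crun, p2, format = "mzml")
  expect_equal(read_run(p2)$metadata$mode, "centroid")
})

test_that("malformed internal files are rejected", {
  p <- withr::local_tempfile()
  writeLines(c("#gcrun 1", "#mode centroid", "#mz_range 40 1000",
               "#scan_period 0.2", "[scans]", "scan,rt", "1,1.0", "2,1.0",
               "[peaks]", "scan,mz,intensity", "1,100,5", "2,100,5"), p)
  expect_error(read_run(p, format = "internal"), "increasing")
  expect_error(read_run(tempfile(), format = "internal"), "not found")
})
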