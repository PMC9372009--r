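test_that("MSP files round-trip with formatting contract", {
  e1 <- library_entry("2-Ethylhexyl salicylate", c(120.0206, 150.0468),
                      c(500, 999), ri = 1811.2, cas = "118-60-5",
                      compound_class = "UV filter")
  e2 <- library_entry("2-Ethylhexyl salicylate, TMS", c(73.0468, 322.1384),
                      c(999, 400), ri = 1950, derivatized = TRUE)
  lib <- spectral_library(list(e1, e2), source = "unit")
  p <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, p)
  txt <- readLines(p)
  expect_true("150.0468 999" %in% txt)   # 4-decimal m/z, integer intensity
  back <- read_msp(p)
  expect_equal(length(back), 2L)
  expect_equal(back$entries[[1]]$ri, 1811.2)
  expect_equal(back$entries[[1]]$cas, "118-60-5")
  expect_true(back$entries[[2]]$derivatized)
  expect_equal(back$entries[[1]]$spectrum$mz, e1$spectrum$mz)
  expect_equal(back$entries[[1]]$spectrum$rel_intensity,
               e1$spectrum$rel_intensity, tolerance = 1e-3)

  # intensities are normalized to base 999 on write
  e3 <- library_entry("x", c(100, 200), c(5, 10))
  expect_equal(max(e3$spectrum$rel_intensity), 999)

  # a second write/read cycle is the identity (idempotence; the source
  # field records provenance and is excluded)
  p2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(back, p2)
  expect_equal(read_msp(p2)$entries, back$entries)

  # 100-entry simulated library round trip
  big <- simulate_library(100, seed = 12L)
  p3 <- withr::local_tempfile(fileext = ".msp")
  write_msp(big, p3)
  b2 <- read_msp(p3)
  expect_equal(length(b2), 100L)
  expect_equal(vapply(b2$entries, `[[`, character(1), "name"), lib_names(big))
  expect_equal(vapply(b2$entries, `[[`, numeric(1), "ri"),
               vapply(big$entries, `[[`, numeric(1), "ri"), tolerance = 1e-9)

  # empty library -> valid empty file
  p4 <- withr::local_tempfile(fileext = ".msp")
  write_msp(spectral_library(list()), p4)
  expect_equal(length(read_msp(p4)), 0L)
})

test_that("malformed MSP input fails with located parse errors", {
  p <- withr::local_tempfile()
  writeLines(c("Name: broken", "Num Peaks: 0"), p)
  expect_error(read_msp(p), "bad peak count")
  p2 <- withr::local_tempfile()
  writeLines(c("Name: broken", "Num Peaks: 3", "100.0 999", ""), p2)
  expect_error(read_msp(p2), "declares 3 peaks, found 1")
  p3 <- withr::local_tempfile()
  writeLines(c("Name: a", "Name: b", "Num Peaks: 1", "100 999"), p3)
  expect_error(read_msp(p3), "without 'Num Peaks:'")
  expect_error(library_entry("empty", numeric(0), numeric(0)), "non-empty")
  expect_error(spectral_library(list(library_entry("a", 100, 999),
                                     library_entry("a", 120, 999))),
               "duplicate")
})

test_that("library entries are built from simulated standard runs", {
  cfg <- noiseless_config(seed = 31L)
  alk <- simulate_alkane_run(c(7L, 30L), config = cfg)
  truth_entry <- simulate_library(1, seed = 33L,
                                  richness_range = c(8L, 8L))$entries[[1]]
  rt <- as.numeric(ri_to_rt(truth_entry$ri, alk$calibration))
  sim <- simulate_run(list(truth_entry), levels = 1000,
                      config = cfg, rts = rt, duration = rt + 60)
  built <- build_entry_from_run(sim$run, expected_rt = rt,
                                calib = alk$calibration, name = "standard")
  expect_equal(built$name, "standard")
  expect_gte(plain_cosine(
    structure(list(apex_rt = built$rt,
                   ions = data.frame(mz = built$spectrum$mz,
                                     abundance = built$spectrum$rel_intensity)),
              class = "component"),
    truth_entry), 0.99)
  expect_lt(abs(built$ri - truth_entry$ri), 2)

  # no component near the expected rt
  expect_error(build_entry_from_run(sim$run, expected_rt = rt + 200,
                                    calib = alk$calibration, name = "x"),
               "no component")

  # an alkane planted as the standard self-indexes at 100 * carbon number
  c10 <- list(name = "C10-like",
              mz = c(57.0699, 71.0855, 85.1012, 142.1716),
              int = c(999, 600, 350, 60))
  e <- library_entry(c10$name, c10$mz, c10$int)
  rt10 <- alk$calibration$rt[alk$calibration$carbon_n == 10]
  sim10 <- simulate_run(list(e), levels = 1000, config = cfg, rts = rt10,
                        duration = rt10 + 60)
  b10 <- build_entry_from_run(sim10$run, expected_rt = rt10,
                              calib = alk$calibration, name = "C10")
  expect_equal(b10$ri, 1000, tolerance = 0.2)
})

test_that("ambiguous standard runs are reported with candidates", {
  cfg <- noiseless_config(seed = 35L)
  lib2 <- simulate_library(2, seed = 36L, richness_range = c(6L, 6L))
  sim <- simulate_run(lib2, levels = 1000, config = cfg, rts = c(100, 110),
                      duration = 170)
  expect_error(build_entry_from_run(sim$run, expected_rt = 105, calib = NULL,
                                    name = "amb"), "ambiguous")
})

test_that("RT library migration recovers affine distortions exactly", {
  cal <- alkane_calibration(7:30, seq(40, by = 30, length.out = 24))
  lib <- simulate_library(20, seed = 14L)
  # give entries rt (drop ri) under a hidden affine map
  a_true <- 0.98; b_true <- 6
  lib$entries <- lapply(lib$entries, function(e) {
    e$rt <- (as.numeric(ri_to_rt(e$ri, cal)) - b_true) / a_true
    e$ri <- NA_real_
    e
  })
  nm <- lib_names(lib)[c(1, 3, 5, 7, 9, 11, 13, 15, 16, 17, 19, 20)]
  rt_lib <- vapply(lib$entries[match(nm, lib_names(lib))], `[[`, numeric(1), "rt")
  anchors <- data.frame(name = nm, rt_lib = rt_lib,
                        rt_exp = a_true * rt_lib + b_true)
  mig <- migrate_rt_library(lib, anchors, cal)
  expect_equal(mig$fit$a, a_true, tolerance = 1e-9)
  expect_equal(mig$fit$b, b_true, tolerance = 1e-9)
  expect_equal(max(abs(mig$fit$residuals)), 0, tolerance = 1e-9)
  # correct RI assignment after correction
  ris <- vapply(mig$library$entries, `[[`, numeric(1), "ri")
  expect_equal(ris, vapply(lib$entries, function(e)
    as.numeric(rt_to_ri(a_true * e$rt + b_true, cal)), numeric(1)),
    tolerance = 1e-9)

  # identity anchors leave rts unchanged
  anchors_id <- data.frame(name = nm, rt_lib = rt_lib, rt_exp = rt_lib)
  mig_id <- migrate_rt_library(lib, anchors_id, cal)
  expect_equal(vapply(mig_id$library$entries, `[[`, numeric(1), "rt"),
               vapply(lib$entries, `[[`, numeric(1), "rt"), tolerance = 1e-9)

  # errors: too few anchors, unknown anchor name
  expect_error(migrate_rt_library(lib, anchors[1, ], cal), "at least 2")
  bad <- anchors; bad$name[1] <- "nope"
  expect_error(migrate_rt_library(lib, bad, cal), "nope")
})

test_that("noisy-anchor migration matches the closed-form least-squares oracle", {
  cal <- alkane_calibration(7:30, seq(40, by = 30, length.out = 24))
  lib <- simulate_library(12, seed = 15L)
  lib$entries <- lapply(lib$entries, function(e) {
    e$rt <- as.numeric(ri_to_rt(e$ri, cal)); e$ri <- NA_real_; e
  })
  rt_lib <- vapply(lib$entries, `[[`, numeric(1), "rt")
  a_true <- 1.02; b_true <- -4
  set.seed(99)
  noise <- rnorm(12, 0, 0.5)
  anchors <- data.frame(name = lib_names(lib), rt_lib = rt_lib,
                        rt_exp = a_true * rt_lib + b_true + noise)
  mig <- migrate_rt_library(lib, anchors, cal)
  # closed-form normal equations, independent of lm
  x <- rt_lib; y <- anchors$rt_exp
  a_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b_hat <- mean(y) - a_hat * mean(x)
  expect_equal(mig$fit$a, a_hat, tolerance = 1e-12)
  expect_equal(mig$fit$b, b_hat, tolerance = 1e-9)
  # recovered slope within 3 standard errors of truth
  res <- y - (a_hat * x + b_hat)
  se_a <- sqrt(sum(res^2) / 10 / sum((x - mean(x))^2))
  expect_lt(abs(a_hat - a_true), 3 * se_a)
})
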