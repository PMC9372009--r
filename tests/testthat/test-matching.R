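test_that("accurate-mass ion pairing respects tolerance and min m/z", {
  q <- centroid_spectrum(100, c(29.0030, 100.0005, 150.05), c(500, 999, 200))
  e <- library_entry("t", c(29.0027, 100.0000, 120.0), c(400, 999, 100))
  p <- match_ions(q, e, amt_ppm = 50, min_mz = 30)
  expect_equal(nrow(p$pairs), 1L)               # 100.0005 at 5 ppm
  expect_equal(p$pairs$ppm_error, 5, tolerance = 0.01)
  expect_false(29.0027 %in% p$unmatched_lib$mz) # below min m/z: excluded
  expect_true(120.0 %in% p$unmatched_lib$mz)
  expect_true(150.05 %in% p$unmatched_query$mz)

  # 100 ppm away is unmatched at 50 ppm
  q2 <- centroid_spectrum(100, 100.0100, 999)
  e2 <- library_entry("t2", 100.0000, 999)
  expect_equal(nrow(match_ions(q2, e2, 50, 30)$pairs), 0L)

  # conflict resolution: nearest ppm wins, one-to-one
  q3 <- centroid_spectrum(100, c(100.0004, 100.0030), c(100, 999))
  e3 <- library_entry("t3", 100.0000, 999)
  p3 <- match_ions(q3, e3, amt_ppm = 50, min_mz = 30)
  expect_equal(p3$pairs$query_mz, 100.0004)
})

test_that("match factor endpoints, affinity in pwf and scale invariance", {
  e <- library_entry("lib", c(51.0229, 77.0386, 105.0335, 152.0620),
                     c(300, 999, 450, 700))
  # identical query -> 100 for every pwf
  q_id <- centroid_spectrum(1, e$spectrum$mz, e$spectrum$rel_intensity)
  p_id <- match_ions(q_id, e, 50, 30)
  for (pwf in c(0, 0.1, 0.5, 1))
    expect_equal(match_factor(p_id, pwf)$score, 100, tolerance = 1e-9)

  # query = library + 5 extra matrix ions
  extra_mz <- c(60.0211, 73.0468, 207.0329, 281.0511, 355.0694)
  q_sup <- centroid_spectrum(1, sort(c(e$spectrum$mz, extra_mz)),
                             c(e$spectrum$rel_intensity,
                               c(120, 400, 250, 180, 90))[
                                 order(c(e$spectrum$mz, extra_mz))])
  p_sup <- match_ions(q_sup, e, 50, 30)
  mf0 <- match_factor(p_sup, pwf = 0)
  expect_equal(mf0$score, 100, tolerance = 1e-9)  # reverse ignores extras

  # pwf = 1 equals an independent brute-force forward cosine
  w <- function(mz, int) int^0.5 * mz^1.3
  union_mz <- sort(unique(c(e$spectrum$mz, q_sup$mz)))
  lv <- vapply(union_mz, function(m) {
    i <- which(abs(e$spectrum$mz - m) < 1e-9)
    if (length(i)) w(m, e$spectrum$rel_intensity[i]) else 0
  }, numeric(1))
  qv <- vapply(union_mz, function(m) {
    i <- which(abs(q_sup$mz - m) < 1e-9)
    if (length(i)) w(m, q_sup$intensity[i]) else 0
  }, numeric(1))
  f_brute <- sum(lv * qv) / sqrt(sum(lv^2) * sum(qv^2))
  mf1 <- match_factor(p_sup, pwf = 1)
  expect_lt(mf1$score, 100)
  expect_equal(mf1$score, 100 * f_brute, tolerance = 1e-9)

  # affine in pwf between R and F
  for (pwf in c(0.1, 0.25, 0.5, 0.75)) {
    mf <- match_factor(p_sup, pwf)
    expect_equal(mf$score, (1 - pwf) * mf0$score + pwf * mf1$score,
                 tolerance = 1e-9)
  }

  # scale invariance of the composite score
  q_scaled <- centroid_spectrum(1, q_sup$mz, q_sup$intensity * 37.5)
  p_sc <- match_ions(q_scaled, e, 50, 30)
  expect_equal(match_factor(p_sc, 0.3)$score, match_factor(p_sup, 0.3)$score,
               tolerance = 1e-9)

  # empty pairing scores zero
  q_none <- centroid_spectrum(1, 500.1234, 999)
  expect_equal(match_factor(match_ions(q_none, e, 50, 30), 0.5)$score, 0)
})

test_that("trapezoidal retention penalty ramps and rejects", {
  pm_house <- match_params(penalty_free_s = 20, rt_range_s = 20,
                           max_rt_penalty = 20)
  expect_equal(rt_penalty(10, pm_house), 1)
  expect_equal(rt_penalty(20, pm_house), 1)
  expect_true(is.na(rt_penalty(25, pm_house)))      # beyond range: reject

  pm_ramp <- match_params(penalty_free_s = 10, rt_range_s = 30,
                          max_rt_penalty = 20)
  expect_equal(rt_penalty(20, pm_ramp), 0.90)       # ramp midpoint
  expect_equal(rt_penalty(30, pm_ramp), 0.80)
  expect_true(is.na(rt_penalty(30.01, pm_ramp)))
  pm_soft <- match_params(penalty_free_s = 10, rt_range_s = 30,
                          max_rt_penalty = 20, soft_penalty = TRUE)
  expect_equal(rt_penalty(100, pm_soft), 0.80)

  # final score non-increasing in delta rt, equal to raw inside the free window
  deltas <- seq(0, 29, by = 1)
  mult <- vapply(deltas, rt_penalty, numeric(1), pm_ramp)
  expect_true(all(diff(mult) <= 0))
  expect_true(all(mult[deltas <= 10] == 1))
})

test_that("identification picks RI-consistent entries (isomer discrimination)", {
  cal <- alkane_calibration(7:30, seq(40, by = 30, length.out = 24))
  spec_mz <- c(104.0626, 149.0233, 205.0859, 223.0965)
  spec_int <- c(150, 999, 120, 80)
  iso1 <- library_entry("Di-iso-butyl phthalate", spec_mz, spec_int, ri = 1546)
  iso2 <- library_entry("Di-n-butyl phthalate", spec_mz, spec_int, ri = 1587)
  lib <- spectral_library(list(iso1, iso2))
  mk_comp <- function(ri) structure(
    list(apex_rt = as.numeric(ri_to_rt(ri, cal)),
         ions = data.frame(mz = spec_mz, abundance = spec_int,
                           area = spec_int, height = spec_int),
         base_area = 999, n_ions = 4L, model_shape = exp(-((-10:10) / 4)^2)),
    class = "component")
  # RI 1546 and 1587 are 41 units apart = 12.3 s here: inside the 20 s window
  # both isomers survive, so the tie must break deterministically; with a
  # ramped penalty the wrong isomer is penalized and loses
  pm <- match_params(penalty_free_s = 5, rt_range_s = 20, max_rt_penalty = 20)
  for (ri in c(1546, 1587)) {
    ids <- identify_components(list(mk_comp(ri)), lib, cal, pm)
    expect_equal(nrow(ids), 1L)
    expect_equal(ids$entry_name,
                 if (ri == 1546) "Di-iso-butyl phthalate"
                 else "Di-n-butyl phthalate")
    expect_equal(ids$final_score, ids$raw_match * ids$penalty_multiplier)
  }
  # default parameters: both isomers fall inside the 20 s penalty-free
  # window (no penalty), so the |delta rt| tie-break decides - still the
  # RI-consistent entry, deterministically
  for (ri in c(1546, 1587)) {
    ids <- identify_components(list(mk_comp(ri)), lib, cal, match_params())
    expect_equal(nrow(ids), 1L)
    expect_equal(ids$entry_name,
                 if (ri == 1546) "Di-iso-butyl phthalate"
                 else "Di-n-butyl phthalate")
  }
})

test_that("identification applies the match-factor cutoff and max hits", {
  fx <- selfmatch_benchmark()
  comps <- fx$dec$components
  ids <- identify_components(comps, fx$lib, fx$calib, match_params())
  truth <- fx$sim$truth
  expect_equal(sort(unique(ids$entry_name)), sort(truth$name))
  expect_true(all(ids$final_score >= 99))
  # at most one hit per component
  expect_false(any(duplicated(ids$component_id)))
  # raising the cutoff above every score removes all identifications
  none <- identify_components(comps, fx$lib, fx$calib,
                              match_params(min_match_factor = 100.5))
  expect_equal(nrow(none), 0L)
  # missing calibration with an RI-only library is a configuration error
  expect_error(identify_components(comps, fx$lib, NULL, match_params()),
               "calibration")
})
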