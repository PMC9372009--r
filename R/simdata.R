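#' Simulation configuration
#'
#' Defaults emulate the acquisition conditions of the reference screening
#' method: 5 spectra/s over m/z 40-1000 with a resolving power of about 5700
#' at m/z 68 and 8400 at m/z 502 (interpolated linearly in m/z between those
#' two points, held flat outside), 3 s chromatographic FWHM. Signal scaling:
#' a compound planted at concentration `level` has a base-ion chromatographic
#' area of `level * response_factor` counts*s, with the other ions scaled by
#' their relative intensities. Error models: a systematic mass error
#' `ppm_bias`, a per-scan random mass error `ppm_sigma`, a per-ion response
#' jitter `ion_cv` (log-normal, drawn once per ion per run, emulating
#' ion-ratio variability between measurement and library), a per-scan
#' intensity jitter `intensity_cv`, additive detector noise `noise_floor`
#' (counts, per profile point), and column-bleed-style background ions
#' (siloxane analogs at 207/281 Da) at constant intensity `bleed_intensity`.
#'
#' @param seed Integer seed fixing all randomness.
#' @param scan_rate Scans per second.
#' @param mz_range Acquisition m/z range, Da.
#' @param resolution_points 2x2 matrix `(mz, R)` anchoring the resolution
#'   model.
#' @param peak_fwhm_s Chromatographic peak FWHM, seconds.
#' @param tailing_tau_s Exponential tailing time constant (0 = pure
#'   Gaussian).
#' @param ppm_bias,ppm_sigma Systematic / random mass error, ppm.
#' @param ion_cv,intensity_cv Relative intensity error models (see above).
#' @param noise_floor Additive profile-point noise sd, counts.
#' @param bleed_intensity Constant background ion intensity, counts.
#' @param response_factor Base-ion area per concentration unit, counts*s.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, scan_rate = 5, mz_range = c(40, 1000),
                       resolution_points = rbind(c(68, 5700), c(502, 8400)),
                       peak_fwhm_s = 3, tailing_tau_s = 0,
                       ppm_bias = 0, ppm_sigma = 5, ion_cv = 0.15,
                       intensity_cv = 0.03, noise_floor = 20,
                       bleed_intensity = 150, response_factor = 2000) {
  stopifnot(scan_rate > 0, peak_fwhm_s > 0, response_factor > 0)
  structure(list(seed = as.integer(seed), scan_rate = scan_rate,
                 mz_range = as.numeric(mz_range),
                 resolution_points = resolution_points,
                 peak_fwhm_s = peak_fwhm_s, tailing_tau_s = tailing_tau_s,
                 ppm_bias = ppm_bias, ppm_sigma = ppm_sigma, ion_cv = ion_cv,
                 intensity_cv = intensity_cv, noise_floor = noise_floor,
                 bleed_intensity = bleed_intensity,
                 response_factor = response_factor),
            class = "sim_config")
}

# sample one integer from an inclusive range (guards sample()'s scalar rule)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

# resolving power at mass m: linear between anchors, flat outside
resolution_at <- function(mz, config) {
  p <- config$resolution_points
  r <- p[1, 2] + (mz - p[1, 1]) * (p[2, 2] - p[1, 2]) / (p[2, 1] - p[1, 1])
  pmin(pmax(r, min(p[, 2])), max(p[, 2]))
}

#' Simulate an accurate-mass EI spectral library
#'
#' Entries carry 3-40 fragment ions (configurable) with base peak 999,
#' accurate masses built from integer nominal masses plus plausible
#' CHNOClBrS mass defects, and retention indices spread over `ri_range`.
#' Byte-reproducible under `seed`.
#'
#' @param n_compounds Number of entries.
#' @param seed Integer seed.
#' @param richness_range Min/max ions per entry.
#' @param ri_range Retention-index span of the entries.
#' @param mz_max Largest fragment nominal mass.
#' @param ri_spacing `"random"` (uniform draws) or `"even"` (equally spaced
#'   over `ri_range`, guaranteeing baseline-separated elution).
#' @return A [spectral_library()].
#' @export
simulate_library <- function(n_compounds, seed = 1L,
                             richness_range = c(3L, 40L),
                             ri_range = c(950, 2850), mz_max = 650,
                             ri_spacing = c("random", "even")) {
  stopifnot(n_compounds >= 1)
  ri_spacing <- match.arg(ri_spacing)
  set.seed(seed)
  ris <- if (ri_spacing == "even" && n_compounds > 1)
    seq(ri_range[1], ri_range[2], length.out = n_compounds)
  else sort(stats::runif(n_compounds, ri_range[1], ri_range[2]))
  entries <- lapply(seq_len(n_compounds), function(i) {
    k <- sample_range(richness_range[1], richness_range[2])
    nominal <- sort(sample(45:mz_max, k))
    defect <- nominal * stats::runif(k, 2e-4, 8e-4)
    mz <- nominal + defect
    rel <- 999 * stats::runif(k, 0.05, 1)^1.5
    rel[sample(k, 1L)] <- 999
    library_entry(sprintf("Compound_%03d", i), mz, rel, ri = ris[i],
                  compound_class = "simulated")
  })
  spectral_library(entries, source = sprintf("simulated(seed=%d)", seed))
}

# chromatographic peak shape sampled at scan times; integrates to `area`
# (Gaussian, or exponentially modified Gaussian when tau > 0)
peak_shape_at <- function(t, rt, area, fwhm, tau) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (tau <= 0) return(area / (sigma * sqrt(2 * pi)) *
                         exp(-(t - rt)^2 / (2 * sigma^2)))
  # EMG; erfc(x) = 2 pnorm(-x sqrt(2))
  z <- (sigma / tau - (t - rt) / sigma) / sqrt(2)
  area / (2 * tau) * exp(sigma^2 / (2 * tau^2) - (t - rt) / tau) *
    2 * stats::pnorm(-z * sqrt(2))
}

# Plant list -> profile run. Each plant: list(name, rt, level, ions =
# data.frame(mz, rel), tau). The per-ion instance table is expanded to an
# 11-point symmetric profile grid (spacing FWHM/3), so an intensity-weighted
# centroid recovers the planted (erroneous) m/z exactly in the noiseless case.
build_profile_run <- function(plants, config, duration, sample_id = "sim") {
  period <- 1 / config$scan_rate
  scan_t <- seq(period, duration, by = period)
  nscan <- length(scan_t)
  inst <- vector("list", length(plants) + 1L)
  sigma <- config$peak_fwhm_s / 2.3548
  half_span <- 4 * sigma + 4 * max(config$tailing_tau_s, 0)
  for (p in seq_along(plants)) {
    pl <- plants[[p]]
    if (pl$rt < scan_t[1] || pl$rt > duration)
      stop(sprintf("planted rt %.1f s outside run (0, %.1f]", pl$rt, duration))
    tau <- pl$tau %||% config$tailing_tau_s
    win <- which(scan_t >= pl$rt - half_span & scan_t <= pl$rt + half_span)
    if (!length(win)) next
    t <- scan_t[win]
    k <- nrow(pl$ions)
    ion_gain <- exp(stats::rnorm(k, 0, config$ion_cv))
    rows <- vector("list", k)
    for (j in seq_len(k)) {
      area <- pl$level * config$response_factor * pl$ions$rel[j] / 999 *
        ion_gain[j]
      y <- peak_shape_at(t, pl$rt, area, config$peak_fwhm_s, tau)
      if (config$intensity_cv > 0)
        y <- y * exp(stats::rnorm(length(y), 0, config$intensity_cv))
      keep <- y > 1
      if (!any(keep)) next
      ppm <- config$ppm_bias + stats::rnorm(sum(keep), 0, config$ppm_sigma)
      rows[[j]] <- data.frame(scan = win[keep],
                              mz = pl$ions$mz[j] * (1 + ppm * 1e-6),
                              intensity = y[keep])
    }
    inst[[p]] <- do.call(rbind, rows)
  }
  if (config$bleed_intensity > 0) {
    bl_mz <- c(207.0329, 281.0511)
    ppm <- config$ppm_bias +
      stats::rnorm(nscan * length(bl_mz), 0, config$ppm_sigma)
    inst[[length(plants) + 1L]] <- data.frame(
      scan = rep(seq_len(nscan), length(bl_mz)),
      mz = rep(bl_mz, each = nscan) * (1 + ppm * 1e-6),
      intensity = config$bleed_intensity *
        exp(stats::rnorm(nscan * length(bl_mz), 0,
                         max(config$intensity_cv, 0.05))))
  }
  inst <- do.call(rbind, inst)
  scans <- profile_scans_from_instances(inst, scan_t, config)
  ms_run(scans, scan_period = period, mz_range = config$mz_range,
         metadata = list(sample = sample_id, mode = "profile"))
}

# expand centroid-level instances to profile points and assemble scans
profile_scans_from_instances <- function(inst, scan_t, config) {
  nscan <- length(scan_t)
  if (is.null(inst) || nrow(inst) == 0L)
    return(lapply(scan_t, function(rt) profile_spectrum(rt, numeric(0), numeric(0))))
  offs <- -5:5
  w <- exp(-4 * log(2) * (offs / 3)^2)  # grid spacing FWHM/3
  n <- nrow(inst)
  fwhm_mz <- inst$mz / resolution_at(inst$mz, config)
  pts_scan <- rep(inst$scan, each = length(offs))
  pts_mz <- rep(inst$mz, each = length(offs)) +
    rep(fwhm_mz / 3, each = length(offs)) * rep(offs, n)
  pts_int <- rep(inst$intensity, each = length(offs)) * rep(w, n)
  if (config$noise_floor > 0) {
    pts_int <- pts_int + stats::rnorm(length(pts_int), 0, config$noise_floor)
    keep <- pts_int > 0
    pts_scan <- pts_scan[keep]; pts_mz <- pts_mz[keep]; pts_int <- pts_int[keep]
  }
  o <- order(pts_scan, pts_mz)
  pts_scan <- pts_scan[o]; pts_mz <- pts_mz[o]; pts_int <- pts_int[o]
  idx_by_scan <- split(seq_along(pts_scan), factor(pts_scan, levels = seq_len(nscan)))
  lapply(seq_len(nscan), function(s) {
    idx <- idx_by_scan[[s]]
    if (!length(idx)) return(profile_spectrum(scan_t[s], numeric(0), numeric(0)))
    m <- pts_mz[idx]; y <- pts_int[idx]
    grp <- cumsum(c(TRUE, diff(m) >= 1e-5))   # merge coinciding grid points
    gm <- vapply(split(seq_along(m), grp), function(g)
      sum(m[g] * y[g]) / sum(y[g]), numeric(1))
    gi <- vapply(split(y, grp), sum, numeric(1))
    profile_spectrum(scan_t[s], gm, gi)
  })
}

#' Simulate a GC-EI-HRMS run from library entries
#'
#' Each planted compound contributes, per library ion, a chromatographic peak
#' (Gaussian, or exponentially modified when the tailing constant is
#' positive) sampled at the scan rate, rendered as profile m/z peaks with
#' resolution-model widths and the configured mass and intensity errors.
#' Matrix components (see [simulate_matrix_profile()]) and column-bleed ions
#' are added on top. Ground truth records every planted signal.
#'
#' @param entries List of [library_entry()] or a [spectral_library()].
#' @param levels Concentration per entry (recycled).
#' @param calib [alkane_calibration()] used to place entries by their RI
#'   when `rts` is missing.
#' @param config [sim_config()].
#' @param rts Optional explicit retention times, seconds.
#' @param matrix Optional matrix profile from [simulate_matrix_profile()].
#' @param duration Run length, seconds (default: last planted rt + 40 s).
#' @param seed Seed for this run's random draws (default `config$seed`).
#' @param sample_id Metadata label.
#' @return List with `run` (profile-mode [ms_run()]) and `truth`
#'   (data.frame `name`, `rt`, `level`, `is_matrix`).
#' @export
simulate_run <- function(entries, levels, calib = NULL, config = sim_config(),
                         rts = NULL, matrix = NULL, duration = NULL,
                         seed = config$seed, sample_id = "sim") {
  if (inherits(entries, "spectral_library")) entries <- entries$entries
  set.seed(seed)
  n <- length(entries)
  levels <- rep_len(levels, n)
  if (is.null(rts)) {
    ris <- vapply(entries, `[[`, numeric(1), "ri")
    if (anyNA(ris) || is.null(calib))
      stop("either rts or (entry RIs + calib) must be provided")
    rts <- as.numeric(ri_to_rt(ris, calib))
  }
  plants <- lapply(seq_len(n), function(i)
    list(name = entries[[i]]$name, rt = rts[i], level = levels[i],
         ions = data.frame(mz = entries[[i]]$spectrum$mz,
                           rel = entries[[i]]$spectrum$rel_intensity),
         tau = config$tailing_tau_s))
  truth <- data.frame(name = vapply(plants, `[[`, character(1), "name"),
                      rt = rts, level = levels,
                      is_matrix = logical(length(plants)))
  if (!is.null(matrix) && length(matrix$plants)) {
    plants <- c(plants, matrix$plants)
    truth <- rbind(truth, data.frame(
      name = vapply(matrix$plants, `[[`, character(1), "name"),
      rt = vapply(matrix$plants, `[[`, numeric(1), "rt"),
      level = vapply(matrix$plants, `[[`, numeric(1), "level"),
      is_matrix = TRUE))
  }
  if (is.null(duration)) duration <- max(truth$rt) + 40
  run <- build_profile_run(plants, config, duration, sample_id)
  list(run = run, truth = truth)
}

#' Simulate an n-alkane calibration run
#'
#' One marker compound per alkane (ions at the canonical alkyl fragment
#' masses 57.0699/71.0855/85.1012) at the scheduled retention times, plus the
#' matching calibration table.
#'
#' @param carbon_range Inclusive alkane carbon-number range.
#' @param rt_schedule Function `carbon_n -> rt` (seconds) or a numeric vector
#'   parallel to the carbon range; must be strictly increasing.
#' @param config [sim_config()].
#' @param level Planted concentration of each alkane.
#' @return List with `run`, `calibration` ([alkane_calibration()] built from
#'   the schedule) and `truth`.
#' @export
simulate_alkane_run <- function(carbon_range = c(7L, 40L),
                                rt_schedule = function(n) 40 + (n - 7) * 30,
                                config = sim_config(), level = 500) {
  cn <- carbon_range[1]:carbon_range[2]
  rts <- if (is.function(rt_schedule)) rt_schedule(cn) else rt_schedule
  if (length(rts) != length(cn) || any(diff(rts) <= 0))
    stop("rt schedule must be strictly increasing, one rt per alkane")
  set.seed(config$seed)
  h <- 1.00782503; c12 <- 12
  plants <- lapply(seq_along(cn), function(i) {
    mwt <- cn[i] * c12 + (2 * cn[i] + 2) * h
    list(name = sprintf("C%d", cn[i]), rt = rts[i], level = level,
         ions = data.frame(mz = c(57.0699, 71.0855, 85.1012, mwt),
                           rel = c(999, 600, 350, 60)),
         tau = config$tailing_tau_s)
  })
  run <- build_profile_run(plants, config, max(rts) + 40, "alkanes")
  list(run = run, calibration = alkane_calibration(cn, rts),
       truth = data.frame(name = sprintf("C%d", cn), rt = rts,
                          level = level, is_matrix = FALSE))
}

#' Simulate a sample-matrix background profile
#'
#' The matrix is modeled as random pseudo-components. A fraction
#' `p_mimic` of them embed the complete ion set of a randomly chosen library
#' entry (intensities log-normally perturbed) among additional random ions -
#' the classic reverse-search false-positive bait of a rich matrix feature
#' containing a library spectrum. A fraction `p_coelute` is placed within a
#' fraction of a peak width of a randomly chosen library compound's retention
#' time, so low-level analytes acquire interfering ions. The remainder are
#' random features spread uniformly in time. The profile is generated once
#' per experiment and shared across replicate injections.
#'
#' @param n_components Number of matrix components.
#' @param rt_range Time span to populate, seconds.
#' @param lib [spectral_library()] the mimic/co-elution fractions refer to.
#' @param calib [alkane_calibration()] used to place library compounds.
#' @param seed Integer seed.
#' @param level_meanlog,level_sdlog Log-normal concentration distribution of
#'   matrix components (same units as analyte levels).
#' @param p_mimic,p_coelute Fractions described above.
#' @param richness_range Ions per plain matrix component.
#' @return List with `plants` (as consumed by [simulate_run()]).
#' @export
simulate_matrix_profile <- function(n_components = 120, rt_range = c(60, 900),
                                    lib = NULL, calib = NULL, seed = 1L,
                                    level_meanlog = log(50), level_sdlog = 0.6,
                                    p_mimic = 0.25, p_coelute = 0.15,
                                    richness_range = c(4L, 14L)) {
  set.seed(seed)
  plants <- vector("list", n_components)
  lib_rts <- if (!is.null(lib) && !is.null(calib))
    as.numeric(ri_to_rt(vapply(lib$entries, `[[`, numeric(1), "ri"), calib))
  else NULL
  for (i in seq_len(n_components)) {
    u <- stats::runif(1)
    lvl <- stats::rlnorm(1, level_meanlog, level_sdlog)
    rt <- stats::runif(1, rt_range[1], rt_range[2])
    if (!is.null(lib) && u < p_mimic) {
      e <- lib$entries[[sample(length(lib$entries), 1L)]]
      base <- data.frame(mz = e$spectrum$mz,
                         rel = e$spectrum$rel_intensity *
                           exp(stats::rnorm(nrow(e$spectrum), 0, 0.35)))
      k_extra <- sample(seq_len(max(2L, 2L * nrow(base))), 1L)
      extra <- data.frame(
        mz = sample(45:600, k_extra) + stats::runif(k_extra, 2e-4, 8e-4) * 500,
        rel = 999 * stats::runif(k_extra, 0.1, 1)^1.2)
      ions <- rbind(base, extra)
    } else {
      if (!is.null(lib_rts) && u < p_mimic + p_coelute)
        rt <- lib_rts[sample(length(lib_rts), 1L)] + stats::rnorm(1, 0, 0.3)
      k <- sample_range(richness_range[1], richness_range[2])
      nominal <- sort(sample(45:600, k))
      ions <- data.frame(mz = nominal + nominal * stats::runif(k, 2e-4, 8e-4),
                         rel = 999 * stats::runif(k, 0.05, 1)^1.5)
    }
    ions$rel <- ions$rel / max(ions$rel) * 999
    ions <- ions[order(ions$mz), ]
    plants[[i]] <- list(name = sprintf("matrix_%03d", i),
                        rt = max(rt, rt_range[1]), level = lvl,
                        ions = ions, tau = 0)
  }
  list(plants = plants, seed = seed)
}

#' Build a full spiked-replicate screening experiment
#'
#' The standard synthetic benchmark: a spike mixture is planted at each
#' concentration level in `replicates` independent injections sharing one
#' matrix profile (per-replicate noise, mass-error and response draws), with
#' one alkane calibration run for the batch. Deterministic under `seed`.
#'
#' @param lib [spectral_library()] searched during screening.
#' @param spiked Names of the entries actually spiked into the samples
#'   (default: all of `lib`). A suspect library larger than the spike
#'   mixture is what makes name-level false positives observable.
#' @param levels Numeric concentration levels (extract units; the reference
#'   design uses 50 and 500 ng/mL).
#' @param replicates Injections per level (reference design: 5).
#' @param seed Integer seed.
#' @param config [sim_config()].
#' @param matrix_components Number of matrix features shared by all runs.
#' @param alkane_range,rt_schedule Passed to [simulate_alkane_run()].
#' @return List of class `screening_experiment`: `samples` (list with
#'   `run`, `truth`, `level`, `replicate`, `sample`), `truth_table`
#'   (data.frame `sample`, `compound`, `level`, `replicate`), `calibration`,
#'   `alkanes`, `matrix`, `library`, `config`.
#' @export
make_screening_experiment <- function(lib, spiked = NULL, levels = c(50, 500),
                                      replicates = 5L, seed = 1L,
                                      config = sim_config(seed = seed),
                                      matrix_components = 120,
                                      alkane_range = c(7L, 30L),
                                      rt_schedule = function(n) 40 + (n - 7) * 30) {
  if (!length(levels)) stop("levels must be non-empty")
  spiked <- spiked %||% lib_names(lib)
  missing <- setdiff(spiked, lib_names(lib))
  if (length(missing))
    stop("spiked compound(s) not in library: ", paste(missing, collapse = ", "))
  spike_entries <- lib$entries[lib_names(lib) %in% spiked]
  alk <- simulate_alkane_run(alkane_range, rt_schedule, config)
  calib <- alk$calibration
  mat <- simulate_matrix_profile(matrix_components,
                                 rt_range = c(min(calib$rt) + 20,
                                              max(calib$rt) - 20),
                                 lib = lib, calib = calib, seed = seed)
  samples <- list()
  truth_rows <- list()
  for (li in seq_along(levels)) for (r in seq_len(replicates)) {
    sid <- sprintf("L%g_R%d", levels[li], r)
    run_seed <- (seed * 131L + li * 17L + r) %% .Machine$integer.max
    sim <- simulate_run(spike_entries, levels = levels[li], calib = calib,
                        config = config, matrix = mat,
                        duration = max(calib$rt) + 40,
                        seed = run_seed, sample_id = sid)
    samples[[sid]] <- list(run = sim$run, truth = sim$truth,
                           level = levels[li], replicate = r, sample = sid)
    truth_rows[[sid]] <- data.frame(sample = sid, compound = spiked,
                                    level = levels[li], replicate = r)
  }
  structure(list(samples = samples,
                 truth_table = do.call(rbind, truth_rows),
                 calibration = calib, alkanes = alk, matrix = mat,
                 library = lib, config = config),
            class = "screening_experiment")
}
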