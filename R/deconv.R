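#' Deconvolution parameters
#'
#' Defaults follow the optimized screening method: extraction window 0.05 Da
#' (full width), absolute area threshold 10,000 counts, retention-time window
#' size factor 100 (the grouping window is `factor * scan_period / 100`
#' seconds, so factor 100 is one scan period), minimum 3 ion peaks per
#' component, up to 10 ion peak shapes stored for correlation bookkeeping, and
#' a minimum shape correlation of 0.9 for an ion to join a component.
#'
#' @param mz_delta Extraction window, Da (full width).
#' @param min_area Minimum absolute peak area, counts.
#' @param rt_window_size_factor Dimensionless grouping window factor.
#' @param min_ion_peaks Minimum ions per surviving component.
#' @param max_shapes_stored Shapes retained per component for correlation.
#' @param shape_corr_min Minimum Pearson correlation between a candidate
#'   peak's shape and the component's model shape, in `[0, 1]`.
#' @param smooth_window Savitzky-Golay window length in scans (odd); `NULL`
#'   derives it from the expected peak width.
#' @param abundance_measure `"area"` or `"height"`: ion abundance recorded in
#'   components.
#' @return A list of class `deconv_params`.
#' @export
deconv_params <- function(mz_delta = 0.05, min_area = 10000,
                          rt_window_size_factor = 100, min_ion_peaks = 3L,
                          max_shapes_stored = 10L, shape_corr_min = 0.9,
                          smooth_window = NULL,
                          abundance_measure = c("area", "height")) {
  abundance_measure <- match.arg(abundance_measure)
  stopifnot(mz_delta > 0, min_area > 0, rt_window_size_factor > 0,
            min_ion_peaks >= 1, shape_corr_min >= 0, shape_corr_min <= 1)
  structure(list(mz_delta = mz_delta, min_area = min_area,
                 rt_window_size_factor = rt_window_size_factor,
                 min_ion_peaks = as.integer(min_ion_peaks),
                 max_shapes_stored = as.integer(max_shapes_stored),
                 shape_corr_min = shape_corr_min,
                 smooth_window = smooth_window,
                 abundance_measure = abundance_measure),
            class = "deconv_params")
}

SHAPE_POINTS <- 21L   # fixed-length resampled peak shape

#' Detect chromatographic peaks in one extracted-ion chromatogram
#'
#' The trace is smoothed with a Savitzky-Golay filter (window derived from the
#' expected peak width unless given), local maxima are located on the smoothed
#' trace, and each peak is integrated valley-to-valley on the raw trace with
#' the trapezoidal rule. Peaks with area below `params$min_area` are
#' discarded. Flat-topped (saturated) peaks take the midpoint of the flat
#' region as apex.
#'
#' @param eic An EIC from [extract_eics()].
#' @param params [deconv_params()].
#' @param scan_period Seconds per scan (used for shape resampling); inferred
#'   from the trace when `NULL`.
#' @return A data.frame with one row per retained peak: `eic_mz`, `apex_rt`,
#'   `start_rt`, `end_rt`, `height`, `area`, and a list-column `shape`
#'   (normalized fixed-length profile, max 1).
#' @export
detect_peaks <- function(eic, params = deconv_params(), scan_period = NULL) {
  rt <- eic$rt; y <- eic$intensity
  n <- length(y)
  empty <- data.frame(eic_mz = numeric(0), apex_rt = numeric(0),
                      start_rt = numeric(0), end_rt = numeric(0),
                      height = numeric(0), area = numeric(0))
  empty$shape <- list()
  if (n < 5L) return(empty)
  if (is.null(scan_period)) scan_period <- stats::median(diff(rt))
  # a trace whose whole integral is below the area threshold cannot yield a peak
  if (sum(y) * scan_period * 1.01 < params$min_area) return(empty)
  w <- params$smooth_window
  if (is.null(w)) {
    # ~ half the expected 3 s peak base, forced odd, at least 5
    w <- max(5L, as.integer(round(1.5 / scan_period)))
    if (w %% 2L == 0L) w <- w + 1L
  }
  # process contiguous non-zero blocks independently (traces are sparse)
  nz <- y > 0
  r <- rle(nz)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- list()
  for (b in which(r$values)) {
    i0 <- max(1L, starts[b] - 2L); i1 <- min(n, ends[b] + 2L)
    if (i1 - i0 + 1L < 5L) next
    yb <- y[i0:i1]; rtb <- rt[i0:i1]
    if (sum(yb) * scan_period * 1.01 < params$min_area) next
    nb <- length(yb)
    ys <- if (nb > w) signal::sgolayfilt(yb, p = 2, n = w) else yb
    ys[ys < 0] <- 0
    cand <- local_maxima(ys)
    if (!length(cand)) next
    mins <- local_minima(ys)
    for (a in cand) {
      lo <- mins[mins < a]; lo <- if (length(lo)) max(lo) else 1L
      hi <- mins[mins > a]; hi <- if (length(hi)) min(hi) else nb
      if (hi - lo < 2L) next
      seg <- lo:hi
      area <- trapz_area(rtb[seg], yb[seg])
      if (area < params$min_area) next
      apex_rt <- apex_top_centroid(rtb, ys, seg, a)
      # peak m/z: local intensity-weighted mean of the member centroids,
      # not the run-global trace mean (guards against distant near-isobars
      # sharing the trace)
      pk_mz <- eic$target_mz
      if (!is.null(eic$mz)) {
        mzseg <- eic$mz[(i0:i1)[seg]]
        ok <- !is.na(mzseg) & yb[seg] > 0
        if (any(ok))
          pk_mz <- sum(mzseg[ok] * yb[seg][ok]) / sum(yb[seg][ok])
      }
      rows[[length(rows) + 1L]] <- list(
        mz = pk_mz,
        apex_rt = apex_rt, start_rt = rtb[lo], end_rt = rtb[hi],
        height = max(yb[seg]), area = area,
        shape = resample_shape(rtb, ys, apex_rt,
                               (rtb[hi] - rtb[lo]) / 2))
    }
  }
  if (!length(rows)) return(empty)
  out <- data.frame(
    eic_mz = vapply(rows, `[[`, numeric(1), "mz"),
    apex_rt = vapply(rows, `[[`, numeric(1), "apex_rt"),
    start_rt = vapply(rows, `[[`, numeric(1), "start_rt"),
    end_rt = vapply(rows, `[[`, numeric(1), "end_rt"),
    height = vapply(rows, `[[`, numeric(1), "height"),
    area = vapply(rows, `[[`, numeric(1), "area"))
  out$shape <- lapply(rows, `[[`, "shape")
  out
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1L] && y[i] > 0) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L   # walk plateau
      if (j == n || y[j + 1L] < y[j]) {
        out <- c(out, as.integer((i + j) %/% 2L))      # plateau midpoint
        i <- j + 1L
        next
      }
      i <- j
    }
    i <- i + 1L
  }
  out
}

local_minima <- function(y) {
  n <- length(y)
  zero <- which(y == 0)
  if (n < 3L) return(zero)
  d1 <- diff(y)
  inner <- which(d1[-1] > 0 & d1[-length(d1)] < 0) + 1L
  sort(unique(c(zero, inner)))
}

trapz_area <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# Sub-scan apex: intensity-weighted centroid of the smoothed trace's top
# (points within 80% of the apex). Symmetric peaks land on the true apex;
# flat (saturated) tops resolve to the plateau midpoint; falls back to the
# discrete maximum for degenerate segments.
apex_top_centroid <- function(rt, ys, seg, apex_idx) {
  top <- seg[ys[seg] >= 0.8 * ys[apex_idx]]
  # restrict to the contiguous top containing the apex
  top <- top[cumsum(c(TRUE, diff(top) != 1L)) ==
               cumsum(c(TRUE, diff(top) != 1L))[match(apex_idx, top)]]
  if (!length(top) || anyNA(top)) return(rt[apex_idx])
  w <- ys[top] - 0.8 * ys[apex_idx]
  if (sum(w) <= 0) return(rt[apex_idx])
  sum(rt[top] * w) / sum(w)
}

# normalized fixed-length shape resampled on apex +/- half_width seconds
# (half the valley-to-valley base, so co-eluting ions of one compound are
# compared over comparable windows)
resample_shape <- function(rt, y, apex_rt, half_width) {
  grid <- seq(apex_rt - half_width, apex_rt + half_width,
              length.out = SHAPE_POINTS)
  v <- stats::approx(rt, y, xout = grid, yleft = 0, yright = 0)$y
  m <- max(v)
  if (m > 0) v / m else v
}

#' Group co-maximizing ion peaks into deconvoluted components
#'
#' Peaks are processed in decreasing height order. The tallest unclustered
#' peak seeds a component; unclustered peaks whose apex lies within the
#' grouping window `rt_window_size_factor * scan_period / 100` seconds of the
#' seed apex and whose shape correlates with the seed's model shape at
#' Pearson r >= `shape_corr_min` join it. Each peak joins at most one
#' component. At most `max_shapes_stored` member shapes are retained per
#' component for correlation bookkeeping (the component keeps all its ions).
#'
#' @param peaks data.frame of peaks from [detect_peaks()] over all EICs of one
#'   run (rows may come from `rbind`ing per-EIC results).
#' @param params [deconv_params()].
#' @param scan_period Seconds per scan of the source run.
#' @return List of `component` objects: `apex_rt`, `ions` (data.frame `mz`,
#'   `abundance`, `area`, `height`, ascending m/z), `base_area`, `n_ions`,
#'   `model_shape`.
#' @export
build_components <- function(peaks, params = deconv_params(), scan_period) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(list())
  dt <- params$rt_window_size_factor * scan_period / 100
  ord <- order(-peaks$height, peaks$eic_mz)
  free <- rep(TRUE, nrow(peaks))
  comps <- list()
  apexes <- peaks$apex_rt
  for (i in ord) {
    if (!free[i]) next
    seed_shape <- peaks$shape[[i]]
    cand <- which(free & abs(apexes - apexes[i]) <= dt + 1e-9)
    member <- logical(length(cand))
    # max_shapes_stored caps correlation bookkeeping only: the component keeps
    # all member ions, but correlations are always taken against the seed's
    # model shape, so the cap never changes membership here.
    for (k in seq_along(cand)) {
      j <- cand[k]
      if (j == i) { member[k] <- TRUE; next }
      r <- shape_cor(peaks$shape[[j]], seed_shape)
      if (!is.na(r) && r >= params$shape_corr_min) member[k] <- TRUE
    }
    mem <- cand[member]
    free[mem] <- FALSE
    sub <- peaks[mem, , drop = FALSE]
    o <- order(sub$eic_mz)
    sub <- sub[o, , drop = FALSE]
    abundance <- if (params$abundance_measure == "area") sub$area else sub$height
    ions <- data.frame(mz = sub$eic_mz, abundance = abundance,
                       area = sub$area, height = sub$height)
    if (anyDuplicated(ions$mz)) {
      # two valley-separated peaks of one EIC can fall inside the window:
      # they are the same ion, so merge them
      g <- match(ions$mz, unique(ions$mz))
      ions <- data.frame(mz = unique(ions$mz),
                         abundance = as.numeric(tapply(ions$abundance, g, sum)),
                         area = as.numeric(tapply(ions$area, g, sum)),
                         height = as.numeric(tapply(ions$height, g, max)))
    }
    comps[[length(comps) + 1L]] <- structure(
      list(apex_rt = apexes[i], ions = ions, base_area = max(sub$area),
           n_ions = nrow(ions), model_shape = seed_shape),
      class = "component")
  }
  comps[order(vapply(comps, `[[`, numeric(1), "apex_rt"))]
}

shape_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Drop components with too few ions
#'
#' @param components List of components from [build_components()].
#' @param params [deconv_params()]; components with fewer than
#'   `min_ion_peaks` ions are removed, survivors are untouched.
#' @return Filtered component list.
#' @export
filter_components <- function(components, params = deconv_params()) {
  keep <- vapply(components, function(cp) cp$n_ions >= params$min_ion_peaks,
                 logical(1))
  components[keep]
}

#' Composite spectrum of a deconvoluted component
#'
#' Classic EI base-peak normalization: ion abundances are scaled so the most
#' abundant ion is 999.
#'
#' @param comp A component.
#' @return A [centroid_spectrum()] at the component's apex retention time.
#' @export
component_spectrum <- function(comp) {
  ab <- comp$ions$abundance
  centroid_spectrum(comp$apex_rt, comp$ions$mz, ab / max(ab) * 999)
}

#' Deconvolute a run end to end
#'
#' Convenience wrapper: centroid (if profile mode), extract EICs, detect
#' peaks per EIC, group into components, and filter on the minimum ion count.
#'
#' @param run An [ms_run()].
#' @param params [deconv_params()].
#' @param min_points,snr_floor Passed to [centroid_run()].
#' @return List with `components` (filtered), `all_components`, `peaks`
#'   (data.frame), `eics`, and the centroided `run`.
#' @export
deconvolve_run <- function(run, params = deconv_params(), min_points = 3L,
                           snr_floor = 0) {
  crun <- centroid_run(run, min_points = min_points, snr_floor = snr_floor)
  eics <- extract_eics(crun, mz_delta = params$mz_delta)
  sp <- crun$scan_period
  pk_list <- lapply(eics, detect_peaks, params = params, scan_period = sp)
  pk_list <- pk_list[vapply(pk_list, nrow, integer(1)) > 0L]
  peaks <- if (length(pk_list)) do.call(rbind, pk_list) else
    detect_peaks(structure(list(rt = numeric(0), intensity = numeric(0),
                                target_mz = 0), class = "eic"), params, 1)
  all_comps <- build_components(peaks, params, scan_period = sp)
  list(components = filter_components(all_comps, params),
       all_components = all_comps, peaks = peaks, eics = eics, run = crun)
}

#' Write a component list to CSV
#'
#' One row per ion: component id, apex retention time, m/z, abundance, area.
#'
#' @param components List of components.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_components_csv <- function(components, path) {
  rows <- lapply(seq_along(components), function(i) {
    cp <- components[[i]]
    data.frame(component = i, apex_rt = cp$apex_rt, mz = cp$ions$mz,
               abundance = cp$ions$abundance, area = cp$ions$area)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(component = integer(0), apex_rt = numeric(0), mz = numeric(0),
               abundance = numeric(0), area = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
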