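#' Construct a profile-mode mass spectrum
#'
#' A profile spectrum is the raw detector trace of one scan: a strictly
#' increasing sequence of m/z sample points with non-negative intensities.
#'
#' @param rt Scan time in seconds.
#' @param mz Numeric vector of m/z sample points (Da), strictly increasing.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @return An object of class `profile_spectrum`.
#' @export
profile_spectrum <- function(rt, mz, intensity) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("profile m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(rt = as.numeric(rt), mz = mz, intensity = intensity),
            class = "profile_spectrum")
}

#' Construct a centroid-mode mass spectrum
#'
#' @param rt Scan time in seconds.
#' @param mz Unique, ascending centroid m/z values (Da).
#' @param intensity Positive centroid intensities.
#' @return An object of class `centroid_spectrum`.
#' @export
centroid_spectrum <- function(rt, mz, intensity) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("centroid m/z values must be unique and ascending")
  if (length(intensity) && any(intensity <= 0))
    stop("centroid intensities must be positive")
  structure(list(rt = as.numeric(rt), mz = mz, intensity = intensity),
            class = "centroid_spectrum")
}

#' Construct a GC-HRMS run
#'
#' A run is a time-ordered sequence of scans acquired at a nominally constant
#' scan rate over a fixed m/z range. The scan period is inferred as the median
#' inter-scan interval when not supplied; up to 10% timing jitter is tolerated.
#'
#' @param scans List of `profile_spectrum` or `centroid_spectrum` objects,
#'   ordered by retention time.
#' @param scan_period Seconds between scans; inferred from scan times if `NULL`.
#' @param mz_range Length-2 numeric, acquisition m/z range in Da.
#' @param metadata Named list of free-form metadata (sample id, mode, ...).
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(scans, scan_period = NULL, mz_range = c(40, 1000),
                   metadata = list()) {
  rts <- vapply(scans, function(s) s$rt, numeric(1))
  if (length(rts) > 1L) {
    if (any(diff(rts) <= 0)) stop("scan retention times must be strictly increasing")
    if (is.null(scan_period)) scan_period <- stats::median(diff(rts))
  } else if (is.null(scan_period)) scan_period <- NA_real_
  mode <- if (length(scans) && inherits(scans[[1L]], "profile_spectrum"))
    "profile" else "centroid"
  if (is.null(metadata$mode)) metadata$mode <- mode
  structure(list(scans = scans, scan_period = scan_period,
                 mz_range = as.numeric(mz_range), metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf("GC-HRMS run: %d %s scans, scan period %.4g s, m/z %g-%g\n",
              length(x$scans), x$metadata$mode, x$scan_period,
              x$mz_range[1L], x$mz_range[2L]))
  invisible(x)
}

scan_rts <- function(run) vapply(run$scans, function(s) s$rt, numeric(1))

is_profile_run <- function(run)
  length(run$scans) > 0L && inherits(run$scans[[1L]], "profile_spectrum")

#' Read a GC-HRMS run from disk
#'
#' Supports mzML (via the mzR bindings to proteowizard) and the package's
#' internal column-oriented text format (see [write_run()]). Profile versus
#' centroid mode is auto-detected from the file's spectrum representation
#' flags.
#'
#' @param path File path.
#' @param format `"mzml"` or `"internal"`. Guessed from the extension when
#'   missing (`.mzML` -> mzml, anything else -> internal).
#' @return An [ms_run()].
#' @export
read_run <- function(path, format = c("guess", "mzml", "internal")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "internal"
  if (!file.exists(path)) stop("cannot read run: file not found: ", path)
  switch(format, mzml = read_run_mzml(path), internal = read_run_internal(path))
}

read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  hdr <- mzR::header(f)
  pk <- mzR::peaks(f)
  if (nrow(hdr) == 0L)
    return(ms_run(list(), scan_period = NA_real_, metadata = list(source = path)))
  if (is.unsorted(hdr$retentionTime, strictly = TRUE))
    stop("mzML scans are not strictly ordered by retention time")
  profile <- !isTRUE(hdr$centroided[1L])
  ctor <- if (profile) profile_spectrum else centroid_spectrum
  scans <- lapply(seq_len(nrow(hdr)), function(i) {
    m <- pk[[i]]
    ctor(hdr$retentionTime[i], m[, 1L], m[, 2L])
  })
  lo <- suppressWarnings(min(hdr$scanWindowLowerLimit, na.rm = TRUE))
  hi <- suppressWarnings(max(hdr$scanWindowUpperLimit, na.rm = TRUE))
  if (!is.finite(lo)) lo <- floor(min(hdr$lowMZ))
  if (!is.finite(hi)) hi <- ceiling(max(hdr$highMZ))
  ms_run(scans, mz_range = c(lo, hi),
         metadata = list(source = path, mode = if (profile) "profile" else "centroid"))
}

# Internal run format: plain text, two CSV sections.
#   #gcrun 1
#   #mode profile|centroid
#   #mz_range <lo> <hi>
#   #scan_period <s>
#   [scans]      scan,rt
#   [peaks]      scan,mz,intensity
read_run_internal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#gcrun"))
    stop("not an internal gcrun file (missing '#gcrun' header): ", path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), hdr, value = TRUE)
    if (length(ln)) strsplit(sub(paste0("^#", key, " "), "", ln[1L]), " ")[[1L]] else NULL
  }
  mode <- get_hdr("mode")
  mzr <- as.numeric(get_hdr("mz_range"))
  sp <- get_hdr("scan_period")
  sp <- if (length(sp)) as.numeric(sp[sp != "NA"]) else numeric(0)
  i_sc <- match("[scans]", lines)
  i_pk <- match("[peaks]", lines)
  if (is.na(i_sc) || is.na(i_pk)) stop("internal run file lacks [scans]/[peaks] sections")
  sc <- utils::read.csv(text = lines[(i_sc + 1L):(i_pk - 1L)])
  pk_lines <- lines[(i_pk + 1L):length(lines)]
  pk <- utils::read.csv(text = pk_lines)
  if (any(duplicated(sc$rt)) || is.unsorted(sc$rt, strictly = TRUE))
    stop("internal run file: scan rts must be strictly increasing")
  ctor <- if (identical(mode, "profile")) profile_spectrum else centroid_spectrum
  byscan <- split(pk[c("mz", "intensity")], factor(pk$scan, levels = sc$scan))
  scans <- lapply(seq_len(nrow(sc)), function(i) {
    p <- byscan[[i]]
    o <- order(p$mz)
    ctor(sc$rt[i], p$mz[o], p$intensity[o])
  })
  ms_run(scans, scan_period = if (length(sp)) sp else NULL, mz_range = mzr,
         metadata = list(source = path, mode = mode))
}

#' Write a GC-HRMS run to disk
#'
#' Round-trips with [read_run()]: `read_run(write_run(x))` equals `x` within
#' 1e-6 relative tolerance on m/z and intensity for both formats.
#'
#' @param run An [ms_run()].
#' @param path Output file path.
#' @param format `"mzml"` or `"internal"`.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, format = c("guess", "mzml", "internal")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "internal"
  switch(format, mzml = write_run_mzml(run, path), internal = write_run_internal(run, path))
  invisible(path)
}

write_run_internal <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("#gcrun 1",
           paste("#mode", run$metadata$mode),
           paste("#mz_range", run$mz_range[1L], run$mz_range[2L]))
  if (length(run$scan_period) && is.finite(run$scan_period))
    hdr <- c(hdr, paste("#scan_period", format(run$scan_period, digits = 12)))
  writeLines(hdr, con)
  writeLines("[scans]", con)
  rts <- scan_rts(run)
  writeLines("scan,rt", con)
  if (length(rts))
    writeLines(paste(seq_along(rts), format(rts, digits = 12), sep = ","), con)
  writeLines("[peaks]", con)
  writeLines("scan,mz,intensity", con)
  for (i in seq_along(run$scans)) {
    s <- run$scans[[i]]
    if (length(s$mz))
      writeLines(paste(i, sprintf("%.6f", s$mz), format(s$intensity, digits = 12),
                       sep = ","), con)
  }
}

write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  n <- length(run$scans)
  profile <- is_profile_run(run)
  if (n == 0L) {
    # proteowizard needs at least a header frame; emit an empty spectrum list
    # via the internal format is not allowed here, so write a 0-spectrum mzML.
    mzR::writeMSData(list(), file = path,
                     header = empty_mzml_header(), outformat = "mzml")
    return(invisible(path))
  }
  pks <- lapply(run$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  rts <- scan_rts(run)
  hdr <- empty_mzml_header(n)
  hdr$seqNum <- hdr$acquisitionNum <- seq_len(n)
  hdr$peaksCount <- vapply(run$scans, function(s) length(s$mz), integer(1))
  hdr$totIonCurrent <- vapply(run$scans, function(s) sum(s$intensity), numeric(1))
  hdr$retentionTime <- rts
  bp <- function(s) if (length(s$mz)) which.max(s$intensity) else NA_integer_
  hdr$basePeakMZ <- vapply(run$scans, function(s) { i <- bp(s); if (is.na(i)) 0 else s$mz[i] }, numeric(1))
  hdr$basePeakIntensity <- vapply(run$scans, function(s) { i <- bp(s); if (is.na(i)) 0 else s$intensity[i] }, numeric(1))
  hdr$lowMZ <- vapply(run$scans, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1))
  hdr$highMZ <- vapply(run$scans, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1))
  hdr$spectrumId <- paste0("scan=", seq_len(n))
  hdr$centroided <- !profile
  hdr$scanWindowLowerLimit <- run$mz_range[1L]
  hdr$scanWindowUpperLimit <- run$mz_range[2L]
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

empty_mzml_header <- function(n = 0L) {
  data.frame(
    seqNum = integer(n), acquisitionNum = integer(n), msLevel = rep(1L, n),
    polarity = rep(0L, n), peaksCount = integer(n), totIonCurrent = numeric(n),
    retentionTime = numeric(n), basePeakMZ = numeric(n),
    basePeakIntensity = numeric(n), collisionEnergy = numeric(n),
    ionisationEnergy = rep(70, n), lowMZ = numeric(n), highMZ = numeric(n),
    precursorScanNum = integer(n), precursorMZ = numeric(n),
    precursorCharge = integer(n), precursorIntensity = numeric(n),
    mergedScan = integer(n), mergedResultScanNum = integer(n),
    mergedResultStartScanNum = integer(n), mergedResultEndScanNum = integer(n),
    injectionTime = numeric(n), filterString = rep(NA_character_, n),
    spectrumId = character(n), centroided = logical(n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = numeric(n), scanWindowUpperLimit = numeric(n),
    stringsAsFactors = FALSE)
}

#' Convert one profile spectrum to centroids
#'
#' Splits the profile into contiguous regions above the intensity floor, one
#' region per local maximum (overlapping maxima are separated at the valley
#' between them). Each region with at least `min_points` points yields a
#' centroid whose m/z is the intensity-weighted mean of the region's sample
#' points and whose intensity is the region's apex intensity.
#'
#' @param spec A [profile_spectrum()].
#' @param min_points Minimum contiguous points above the floor per centroid.
#' @param snr_floor Intensity floor in counts; points at or below it are
#'   treated as baseline.
#' @return A [centroid_spectrum()].
#' @export
centroid_profile <- function(spec, min_points = 3L, snr_floor = 0) {
  stopifnot(inherits(spec, "profile_spectrum"))
  x <- spec$mz; y <- spec$intensity
  keep <- y > snr_floor
  if (!any(keep)) return(centroid_spectrum(spec$rt, numeric(0), numeric(0)))
  # contiguous runs above the floor
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cm <- numeric(0); ci <- numeric(0)
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    # stored profiles are sparse: points of distinct ions can be adjacent in
    # index space, so split first at m/z gaps far beyond the sampling pitch
    # (250 ppm vs ~40-60 ppm point spacing at typical TOF resolving power)
    xr <- x[i0:i1]
    gap_grp <- cumsum(c(TRUE, diff(xr) > 2.5e-4 * xr[-length(xr)]))
    for (g in split(seq_along(xr), gap_grp)) {
      j0 <- i0 + g[1L] - 1L; j1 <- i0 + g[length(g)] - 1L
      seg <- split_at_valleys(y[j0:j1])
      for (s in seg) {
        idx <- (j0 + s[1L] - 1L):(j0 + s[2L] - 1L)
        if (length(idx) < min_points) next
        w <- y[idx]
        cm <- c(cm, sum(x[idx] * w) / sum(w))
        ci <- c(ci, max(w))
      }
    }
  }
  if (!length(cm)) return(centroid_spectrum(spec$rt, numeric(0), numeric(0)))
  o <- order(cm)
  cm <- cm[o]; ci <- ci[o]
  dup <- c(FALSE, diff(cm) <= 0)
  centroid_spectrum(spec$rt, cm[!dup], ci[!dup])
}

# Split one above-floor segment into sub-segments, one per resolved local
# maximum. A cut between two maxima is made only when the valley drops below
# half the smaller of the two apexes, so sampling noise on a single peak does
# not fragment it. Returns a list of (start, end) index pairs relative to the
# segment.
split_at_valleys <- function(y) {
  n <- length(y)
  if (n < 3L) return(list(c(1L, n)))
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(is_max) <= 1L) return(list(c(1L, n)))
  cuts <- integer(0)
  j <- 1L
  left_apex <- y[is_max[1L]]
  for (k in 2:length(is_max)) {
    between <- (is_max[j] + 1L):(is_max[k] - 1L)
    if (!length(between)) between <- is_max[j]
    v <- between[which.min(y[between])]
    if (y[v] < 0.5 * min(left_apex, y[is_max[k]])) {
      cuts <- c(cuts, v)
      j <- k
      left_apex <- y[is_max[k]]
    } else left_apex <- max(left_apex, y[is_max[k]])
  }
  bounds <- c(1L, cuts, n)
  lapply(seq_len(length(bounds) - 1L), function(j)
    c(if (j == 1L) 1L else bounds[j] + 1L, bounds[j + 1L]))
}

#' Centroid every scan of a profile-mode run
#'
#' @inheritParams centroid_profile
#' @param run A profile-mode [ms_run()].
#' @return A centroid-mode [ms_run()] with the same scan times.
#' @export
centroid_run <- function(run, min_points = 3L, snr_floor = 0) {
  if (!is_profile_run(run)) return(run)
  scans <- lapply(run$scans, centroid_profile, min_points = min_points,
                  snr_floor = snr_floor)
  md <- run$metadata
  md$mode <- "centroid"
  ms_run(scans, scan_period = run$scan_period, mz_range = run$mz_range,
         metadata = md)
}

#' Extract ion chromatograms from a centroided run
#'
#' Clusters centroid peaks across scans into mass traces (EICs). `mz_delta` is
#' the FULL window width: any two peaks assigned to one EIC differ by at most
#' `mz_delta` Da (set `half_window = TRUE` to interpret it as a half-window).
#' Trace building is greedy in decreasing intensity order with nearest-mass
#' assignment, ties broken toward lower m/z; each peak joins exactly one EIC,
#' so total ion current is conserved. Scans without a member peak contribute
#' intensity zero.
#'
#' @param run Centroid-mode [ms_run()].
#' @param mz_delta Extraction window in Da (default 0.05, the full width).
#' @param half_window If `TRUE`, `mz_delta` is doubled before use.
#' @return List of `eic` objects with fields `target_mz`, `mz_delta`, `rt`,
#'   `intensity` (dense, one value per scan).
#' @export
extract_eics <- function(run, mz_delta = 0.05, half_window = FALSE) {
  if (is_profile_run(run))
    stop("extract_eics requires a centroided run; call centroid_run() first")
  if (half_window) mz_delta <- 2 * mz_delta
  rts <- scan_rts(run)
  nscan <- length(rts)
  mzs <- unlist(lapply(run$scans, `[[`, "mz"))
  if (!length(mzs)) return(list())
  ints <- unlist(lapply(run$scans, `[[`, "intensity"))
  scan_of <- rep.int(seq_len(nscan),
                     vapply(run$scans, function(s) length(s$mz), integer(1)))
  o <- order(mzs)
  mzs <- mzs[o]; ints <- ints[o]; scan_of <- scan_of[o]
  # coarse pre-clustering: independent chunks split at mass gaps > mz_delta
  gap <- which(diff(mzs) > mz_delta)
  chunk_id <- cumsum(c(1L, seq_along(mzs)[-1L] %in% (gap + 1L)))
  out <- list()
  for (ck in split(seq_along(mzs), chunk_id)) {
    assigns <- greedy_traces(mzs[ck], ints[ck], scan_of[ck], mz_delta)
    for (tr in assigns) {
      idx <- ck[tr]
      trace <- numeric(nscan)
      trace[scan_of[idx]] <- ints[idx]
      mz_trace <- rep(NA_real_, nscan)
      mz_trace[scan_of[idx]] <- mzs[idx]
      tmz <- sum(mzs[idx] * ints[idx]) / sum(ints[idx])
      out[[length(out) + 1L]] <- structure(
        list(target_mz = tmz, mz_delta = mz_delta, rt = rts,
             intensity = trace, mz = mz_trace),
        class = "eic")
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "target_mz"))]
}

# Greedy trace building within one mass chunk. Peaks are visited in
# decreasing intensity order; each joins the open trace with the nearest
# target m/z whose full-window and one-peak-per-scan constraints it satisfies,
# else it seeds a new trace. Ties go to the lower-m/z trace.
greedy_traces <- function(mz, int, scan, mz_delta) {
  n <- length(mz)
  if (n == 1L) return(list(1L))
  ord <- order(-int, mz)
  tr_members <- list()          # member indices per trace
  tr_min <- tr_max <- tr_mz <- numeric(0)
  tr_scans <- list()
  for (i in ord) {
    best <- 0L; best_d <- Inf
    if (length(tr_mz)) {
      for (t in seq_along(tr_mz)) {
        if (mz[i] < tr_max[t] - mz_delta || mz[i] > tr_min[t] + mz_delta) next
        if (scan[i] %in% tr_scans[[t]]) next
        d <- abs(mz[i] - tr_mz[t])
        if (d < best_d - 1e-12 || (abs(d - best_d) <= 1e-12 && best > 0L &&
                                   tr_mz[t] < tr_mz[best])) {
          best <- t; best_d <- d
        }
      }
    }
    if (best == 0L) {
      tr_members[[length(tr_members) + 1L]] <- i
      tr_min <- c(tr_min, mz[i]); tr_max <- c(tr_max, mz[i])
      tr_mz <- c(tr_mz, mz[i])
      tr_scans[[length(tr_members)]] <- scan[i]
    } else {
      m <- c(tr_members[[best]], i)
      tr_members[[best]] <- m
      tr_min[best] <- min(tr_min[best], mz[i])
      tr_max[best] <- max(tr_max[best], mz[i])
      tr_mz[best] <- sum(mz[m] * int[m]) / sum(int[m])
      tr_scans[[best]] <- c(tr_scans[[best]], scan[i])
    }
  }
  tr_members
}

#' Total ion current of a run or EIC set
#'
#' @param x An [ms_run()] (centroided) or a list of EICs from [extract_eics()].
#' @return Numeric vector, one TIC value per scan.
#' @export
total_ion_current <- function(x) {
  if (inherits(x, "ms_run"))
    return(vapply(x$scans, function(s) sum(s$intensity), numeric(1)))
  if (length(x) == 0L) return(numeric(0))
  Reduce(`+`, lapply(x, `[[`, "intensity"))
}
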