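#' Construct an accurate-mass EI library entry
#'
#' @param name Compound name (derivatized variants conventionally suffixed
#'   `", TMS"`).
#' @param mz Fragment m/z values, Da.
#' @param intensity Relative intensities; normalized to base peak 999.
#' @param ri Kovats retention index, or `NA`.
#' @param rt Retention time in seconds, or `NA`.
#' @param cas CAS registry number, or `""`.
#' @param derivatized `TRUE` for trimethylsilyl (TMS) derivatives.
#' @param compound_class Free-form class label.
#' @param mw Molecular weight, Da, optional.
#' @param logkow log octanol-water partition coefficient, optional.
#' @return An object of class `library_entry`.
#' @export
library_entry <- function(name, mz, intensity, ri = NA_real_, rt = NA_real_,
                          cas = "", derivatized = FALSE, compound_class = "",
                          mw = NA_real_, logkow = NA_real_) {
  if (!length(mz)) stop("library entry needs a non-empty spectrum: ", name)
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  if (any(intensity <= 0)) stop("library intensities must be positive: ", name)
  intensity <- intensity / max(intensity) * 999
  structure(list(name = name, cas = cas, ri = as.numeric(ri),
                 rt = as.numeric(rt), derivatized = isTRUE(derivatized),
                 spectrum = data.frame(mz = mz, rel_intensity = intensity),
                 compound_class = compound_class, mw = mw, logkow = logkow),
            class = "library_entry")
}

#' Construct a spectral library
#'
#' @param entries List of [library_entry()] objects; names must be unique.
#' @param source Free-form provenance string.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(entries, source = "") {
  nms <- vapply(entries, `[[`, character(1), "name")
  if (any(duplicated(nms)))
    stop("duplicate entry names in library: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(list(entries = entries, source = source),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("EI spectral library: %d entries%s\n", length(x$entries),
              if (nzchar(x$source)) paste0(" (", x$source, ")") else ""))
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$entries)

#' Entry names of a spectral library
#'
#' @param lib A [spectral_library()].
#' @return Character vector of entry names.
#' @export
lib_names <- function(lib) vapply(lib$entries, `[[`, character(1), "name")

#' Read an MSP-dialect spectral library
#'
#' NIST-compatible MSP superset: `Name:`, optional `CASNO:`, `RI:`, `RT:`
#' (seconds), `MW:`, `Comments:` with `key=value` tokens (including
#' `derivatized=TMS`, `class=...`, `logkow=...`), then `Num Peaks:` followed
#' by whitespace-separated m/z intensity pairs.
#'
#' @param path MSP file path.
#' @return A [spectral_library()].
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  entries <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !grepl("^Name:", lines[i])) {
      if (nzchar(trimws(lines[i])))
        stop(sprintf("MSP parse error at line %d: expected 'Name:' got '%s'",
                     i, lines[i]))
      i <- i + 1L
    }
    if (i > n) break
    fields <- list(name = trimws(sub("^Name:", "", lines[i])))
    i <- i + 1L
    npk <- NA_integer_
    while (i <= n && !grepl("^Num Peaks:", lines[i])) {
      ln <- lines[i]
      if (grepl("^CASNO:", ln)) fields$cas <- trimws(sub("^CASNO:", "", ln))
      else if (grepl("^RI:", ln)) fields$ri <- as.numeric(sub("^RI:", "", ln))
      else if (grepl("^RT:", ln)) fields$rt <- as.numeric(sub("^RT:", "", ln))
      else if (grepl("^MW:", ln)) fields$mw <- as.numeric(sub("^MW:", "", ln))
      else if (grepl("^Comments:", ln)) {
        toks <- strsplit(trimws(sub("^Comments:", "", ln)), "[ ;]+")[[1L]]
        kv <- strsplit(toks, "=")
        for (p in kv) if (length(p) == 2L) {
          if (p[1L] == "derivatized") fields$derivatized <- identical(p[2L], "TMS")
          if (p[1L] == "class") fields$compound_class <- gsub("_", " ", p[2L])
          if (p[1L] == "logkow") fields$logkow <- as.numeric(p[2L])
        }
      } else if (grepl("^Name:", ln))
        stop(sprintf("MSP parse error at line %d: entry without 'Num Peaks:'", i))
      i <- i + 1L
    }
    if (i > n)
      stop(sprintf("MSP parse error: entry '%s' lacks 'Num Peaks:'", fields$name))
    npk <- as.integer(trimws(sub("^Num Peaks:", "", lines[i])))
    if (is.na(npk) || npk < 1L)
      stop(sprintf("MSP parse error at line %d: bad peak count for '%s'",
                   i, fields$name))
    i <- i + 1L
    mzv <- numeric(0); iv <- numeric(0)
    while (i <= n && length(mzv) < npk && nzchar(trimws(lines[i]))) {
      vals <- as.numeric(strsplit(trimws(lines[i]), "[ \t;]+")[[1L]])
      if (length(vals) %% 2L != 0L || anyNA(vals))
        stop(sprintf("MSP parse error at line %d: bad peak line", i))
      mzv <- c(mzv, vals[c(TRUE, FALSE)])
      iv <- c(iv, vals[c(FALSE, TRUE)])
      i <- i + 1L
    }
    if (length(mzv) != npk)
      stop(sprintf("MSP parse error near line %d: '%s' declares %d peaks, found %d",
                   i, fields$name, npk, length(mzv)))
    entries[[length(entries) + 1L]] <- library_entry(
      name = fields$name, mz = mzv, intensity = iv,
      ri = fields$ri %||% NA_real_, rt = fields$rt %||% NA_real_,
      cas = fields$cas %||% "", derivatized = fields$derivatized %||% FALSE,
      compound_class = fields$compound_class %||% "",
      mw = fields$mw %||% NA_real_, logkow = fields$logkow %||% NA_real_)
  }
  spectral_library(entries, source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectral library in MSP dialect
#'
#' m/z values are written with 4 decimals and intensities as integers 1-999
#' after base-peak normalization, so a write/read cycle is idempotent.
#'
#' @param lib A [spectral_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in lib$entries) {
    writeLines(paste0("Name: ", e$name), con)
    if (nzchar(e$cas)) writeLines(paste0("CASNO: ", e$cas), con)
    if (!is.na(e$ri)) writeLines(paste0("RI: ", format(e$ri, digits = 10)), con)
    if (!is.na(e$rt)) writeLines(paste0("RT: ", format(e$rt, digits = 10)), con)
    if (!is.na(e$mw)) writeLines(paste0("MW: ", format(e$mw, digits = 10)), con)
    comments <- character(0)
    if (e$derivatized) comments <- c(comments, "derivatized=TMS")
    if (nzchar(e$compound_class))
      comments <- c(comments, paste0("class=", gsub(" ", "_", e$compound_class)))
    if (!is.na(e$logkow)) comments <- c(comments, paste0("logkow=", e$logkow))
    if (length(comments))
      writeLines(paste0("Comments: ", paste(comments, collapse = " ")), con)
    ri_int <- pmax(1L, as.integer(round(e$spectrum$rel_intensity)))
    writeLines(paste0("Num Peaks: ", nrow(e$spectrum)), con)
    writeLines(sprintf("%.4f %d", e$spectrum$mz, ri_int), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Build a library entry from a standard-compound run
#'
#' Deconvolutes the run, locates the dominant component within +/- 15 s of the
#' expected retention time, and records its base-999 spectrum together with
#' the apex retention time and the Kovats RI from the batch's alkane
#' calibration. This is the workflow used to build an in-house library from
#' individually injected standards run with a C7-C40 alkane mix.
#'
#' @param run An [ms_run()] of a single injected standard.
#' @param expected_rt Expected retention time, seconds.
#' @param calib [alkane_calibration()] acquired under the same program.
#' @param name Entry name.
#' @param deconv_params [deconv_params()].
#' @param rt_tol Search half-window around `expected_rt` (default 15 s).
#' @param ... Passed to [library_entry()] (cas, derivatized, ...).
#' @return A [library_entry()] with `ri` and `rt` set.
#' @export
build_entry_from_run <- function(run, expected_rt, calib, name,
                                 deconv_params = gcscreen::deconv_params(),
                                 rt_tol = 15, ...) {
  dec <- deconvolve_run(run, deconv_params)
  comps <- dec$components
  if (!length(comps)) stop("no component found near expected rt for ", name)
  rts <- vapply(comps, `[[`, numeric(1), "apex_rt")
  near <- which(abs(rts - expected_rt) <= rt_tol)
  if (!length(near)) stop("no component found near expected rt for ", name)
  areas <- vapply(comps[near], `[[`, numeric(1), "base_area")
  o <- order(-areas)
  if (length(near) > 1L && areas[o[2L]] >= 0.5 * areas[o[1L]])
    stop(sprintf(
      "ambiguous standard run for %s: %d comparable components near %.1f s (rts %s)",
      name, sum(areas >= 0.5 * areas[o[1L]]), expected_rt,
      paste(sprintf("%.1f", rts[near][areas >= 0.5 * areas[o[1L]]]), collapse = ", ")))
  best <- comps[[near[o[1L]]]]
  spec <- component_spectrum(best)
  library_entry(name, spec$mz, spec$intensity,
                ri = as.numeric(rt_to_ri(best$apex_rt, calib)),
                rt = best$apex_rt, ...)
}

#' Migrate an RT-annotated library to retention indices
#'
#' Fits an ordinary least-squares linear correction
#' `rt_exp = a * rt_lib + b` over anchor compounds measured under the current
#' chromatographic program, maps every entry's library retention time through
#' it, and converts the corrected times to Kovats RIs with the batch alkane
#' calibration. This mirrors the migration of a vendor retention-time-locked
#' library (12 anchors spanning the calibrated range are typical).
#'
#' @param lib [spectral_library()] whose entries carry `rt`.
#' @param anchors data.frame with columns `name`, `rt_lib`, `rt_exp`
#'   (seconds); at least 2 rows, names must exist in `lib`.
#' @param calib [alkane_calibration()].
#' @return List with `library` (entries updated: corrected `rt`, new `ri`)
#'   and `fit` (`a`, `b`, `r_squared`, `residuals`).
#' @export
migrate_rt_library <- function(lib, anchors, calib) {
  if (nrow(anchors) < 2L) stop("need at least 2 anchors for the linear correction")
  missing <- setdiff(anchors$name, lib_names(lib))
  if (length(missing))
    stop("anchor name(s) not in library: ", paste(missing, collapse = ", "))
  fit <- stats::lm(rt_exp ~ rt_lib, data = anchors)
  a <- unname(stats::coef(fit)[2L]); b <- unname(stats::coef(fit)[1L])
  entries <- lapply(lib$entries, function(e) {
    if (is.na(e$rt)) return(e)
    e$rt <- a * e$rt + b
    e$ri <- as.numeric(rt_to_ri(e$rt, calib))
    e
  })
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((anchors$rt_exp - mean(anchors$rt_exp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  list(library = spectral_library(entries, source = lib$source),
       fit = list(a = a, b = b, r_squared = r2, residuals = res))
}
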