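#' n-Alkane retention calibration
#'
#' A calibration maps retention time to Kovats retention index through a
#' homologous series of n-alkanes (C7-C40 in the reference method): alkane
#' Cn defines RI = 100 n, and queries are interpolated linearly between the
#' bracketing alkanes (the van den Dool-Kratz form appropriate for
#' temperature-programmed separations).
#'
#' @param carbon_n Integer alkane carbon numbers, strictly increasing.
#' @param rt Retention times in seconds, strictly increasing, same length.
#' @return An object of class `alkane_calibration` with fields `carbon_n`,
#'   `rt`, `ri` (= 100 * carbon_n).
#' @export
alkane_calibration <- function(carbon_n, rt) {
  o <- order(carbon_n)
  carbon_n <- as.integer(carbon_n[o]); rt <- as.numeric(rt[o])
  if (length(carbon_n) < 2L) stop("calibration needs at least 2 alkanes")
  if (any(duplicated(carbon_n))) stop("duplicate alkane carbon number")
  if (any(diff(rt) <= 0))
    stop("alkane retention times must increase with carbon number")
  structure(list(carbon_n = carbon_n, rt = rt, ri = 100 * carbon_n),
            class = "alkane_calibration")
}

#' @export
print.alkane_calibration <- function(x, ...) {
  cat(sprintf("n-alkane calibration: C%d-C%d, rt %.1f-%.1f s (%d points)\n",
              min(x$carbon_n), max(x$carbon_n), min(x$rt), max(x$rt),
              length(x$rt)))
  invisible(x)
}

#' Read a calibration retention time (CRT) table
#'
#' CSV with columns `name`, `rt`, `ri`; `ri` must be multiples of 100 (the
#' alkane Kovats convention), from which carbon numbers are inferred. Rows may
#' be in any order. Retention times are in seconds unless the `rt` column is
#' named `rt_min` (minutes) or `unit` is given.
#'
#' @param path CSV path.
#' @param unit `"s"` or `"min"` for the rt column.
#' @return An [alkane_calibration()].
#' @export
load_crt <- function(path, unit = c("s", "min")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  if (("rt_min" %in% names(df)) && !("rt" %in% names(df))) {
    df$rt <- df$rt_min; unit <- "min"
  }
  if (!all(c("name", "rt", "ri") %in% names(df)))
    stop("CRT file must have columns name, rt, ri: ", path)
  if (any(df$ri %% 100 != 0))
    stop("CRT ri values must be multiples of 100 (alkane convention)")
  rt <- if (unit == "min") df$rt * 60 else df$rt
  alkane_calibration(df$ri / 100, rt)
}

#' Write a CRT table
#'
#' @param calib An [alkane_calibration()].
#' @param path Output CSV path (rt written in seconds).
#' @return `path`, invisibly.
#' @export
write_crt <- function(calib, path) {
  df <- data.frame(name = sprintf("C%d", calib$carbon_n),
                   rt = calib$rt, ri = calib$ri)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert retention time to Kovats retention index
#'
#' Piecewise linear between bracketing alkanes:
#' `RI = 100 n + 100 (rt - t_n) / (t_{n+1} - t_n)` for `t_n <= rt <= t_{n+1}`.
#' Queries outside the calibrated range are linearly extrapolated from the
#' nearest bracket and flagged via the `"extrapolated"` attribute.
#'
#' @param rt Retention time(s), seconds.
#' @param calib An [alkane_calibration()].
#' @return Numeric RI value(s) with logical attribute `extrapolated`.
#' @export
rt_to_ri <- function(rt, calib) {
  ri <- interp_extrap(calib$rt, calib$ri, rt)
  attr(ri, "extrapolated") <- rt < min(calib$rt) | rt > max(calib$rt)
  ri
}

#' Convert Kovats retention index to retention time
#'
#' Exact inverse of [rt_to_ri()] on the calibrated range; extrapolated
#' outside it (flagged).
#'
#' @param ri Retention index value(s).
#' @param calib An [alkane_calibration()].
#' @return Retention time(s) in seconds with attribute `extrapolated`.
#' @export
ri_to_rt <- function(ri, calib) {
  rt <- interp_extrap(calib$ri, calib$rt, ri)
  attr(rt, "extrapolated") <- ri < min(calib$ri) | ri > max(calib$ri)
  rt
}

# piecewise-linear interpolation with linear extrapolation from the
# outermost segments (x strictly increasing)
interp_extrap <- function(x, y, xout) {
  n <- length(x)
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= n] <- n - 1L
  y[i] + (xout - x[i]) * (y[i + 1L] - y[i]) / (x[i + 1L] - x[i])
}
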