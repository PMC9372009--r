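#' Score identifications against a spike truth table
#'
#' True positives are truth compounds with at least one identification
#' matching by name; false negatives are truth compounds with none; false
#' positives are identifications whose name is not in the truth set (matrix
#' or background hits count as false positives).
#'
#' @param ids An `identification_set` from [identify_components()].
#' @param truth Character vector of spiked compound names for this sample.
#' @param libraries Optional [spectral_library()] (or list of them) used to
#'   warn about truth names that are not searchable at all; such compounds
#'   are excluded from the denominator.
#' @return A list of class `eval_result`: `tp`, `fp`, `fn`, `fn_rate`,
#'   `detected` (named logical per truth compound), `fp_names`.
#' @export
score_detections <- function(ids, truth, libraries = NULL) {
  truth <- unique(truth)
  if (!is.null(libraries)) {
    if (inherits(libraries, "spectral_library")) libraries <- list(libraries)
    searchable <- unique(unlist(lapply(libraries, lib_names)))
    absent <- setdiff(truth, searchable)
    if (length(absent)) {
      warning("truth compound(s) absent from the libraries, excluded: ",
              paste(absent, collapse = ", "))
      truth <- setdiff(truth, absent)
    }
  }
  found <- unique(ids$entry_name)
  detected <- stats::setNames(truth %in% found, truth)
  fp_names <- setdiff(found, truth)
  fp <- sum(!(ids$entry_name %in% truth))
  structure(list(tp = sum(detected), fp = fp, fn = sum(!detected),
                 fn_rate = if (length(truth)) mean(!detected) else NA_real_,
                 detected = detected, fp_names = fp_names),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d (FN rate %.1f%%)\n",
              x$tp, x$fp, x$fn, 100 * x$fn_rate))
  invisible(x)
}

#' Match-factor cutoff for a target false-negative rate
#'
#' Given the best final scores of the truth compounds (missed compounds enter
#' as score 0), returns the largest integer cutoff `c` such that the fraction
#' of scores below `c` is at most `target_fn_rate`, with detection defined as
#' score >= c. Cutoffs are integers, matching the reporting convention of
#' screening-method optimization tables.
#'
#' @param scores Numeric vector of best final scores (0-100), one per
#'   compound x replicate; 0 for misses.
#' @param target_fn_rate Allowed false-negative fraction, in `[0, 1)`.
#' @return Integer cutoff.
#' @export
cutoff_for_fn_rate <- function(scores, target_fn_rate) {
  if (!length(scores)) stop("empty score list")
  if (target_fn_rate < 0 || target_fn_rate >= 1)
    stop("target_fn_rate must be in [0, 1)")
  best <- 0L
  for (c in 0:101) if (mean(scores < c) <= target_fn_rate) best <- c
  best
}

#' Sweep accurate mass tolerance and pure weight factor
#'
#' Full-factorial re-evaluation of a set of runs over an AMT x PWF grid.
#' Deconvolution is performed once per run and the pairing/cosine work once
#' per (run, AMT) via [component_scores()]; each grid cell then mixes the
#' cached forward/reverse cosines with its pure weight factor and applies
#' `cutoff_policy`.
#'
#' @param runs List of deconvoluted runs: each element a list with
#'   `components` (from [deconvolve_run()]) and `truth` (character names).
#' @param libraries,calib,params As in [identify_components()]; `params`
#'   supplies everything except `amt_ppm`, `pwf` and `min_match_factor`.
#' @param amt_grid Numeric vector of tolerances, ppm.
#' @param pwf_grid Numeric vector of pure weight factors.
#' @param cutoff_policy A single number (fixed cutoff applied everywhere), or
#'   a function `(amt, pwf) -> cutoff`.
#' @return data.frame: one row per (amt, pwf) with `cutoff`, `tp`, `fp`,
#'   `fn`, `fn_rate_pct`, `fp_per_sample`, `n_samples`.
#' @export
sweep_parameters <- function(runs, libraries, calib, amt_grid, pwf_grid,
                             cutoff_policy = 75, params = match_params()) {
  if (!length(amt_grid) || !length(pwf_grid)) stop("empty parameter grid")
  cutoff_fun <- if (is.function(cutoff_policy)) cutoff_policy
    else function(amt, pwf) cutoff_policy
  rows <- list()
  for (amt in amt_grid) {
    pm <- params
    pm$amt_ppm <- amt
    tabs <- lapply(runs, function(r)
      component_scores(r$components, libraries, calib, pm))
    for (pwf in pwf_grid) {
      cut <- cutoff_fun(amt, pwf)
      tp <- fp <- fn <- 0L
      for (i in seq_along(runs)) {
        ids <- select_hits(tabs[[i]], pwf, cut, pm$max_hits, pm$threshold_on)
        ev <- score_detections(ids, runs[[i]]$truth)
        tp <- tp + ev$tp; fp <- fp + ev$fp; fn <- fn + ev$fn
      }
      rows[[length(rows) + 1L]] <- data.frame(
        amt_ppm = amt, pwf = pwf, cutoff = cut, tp = tp, fp = fp, fn = fn,
        fn_rate_pct = 100 * fn / (tp + fn),
        fp_per_sample = fp / length(runs), n_samples = length(runs))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best final score per truth compound per run
#'
#' Helper for cutoff calibration: identifications are computed with the
#' cutoff disabled, and each truth compound's best final score is recorded
#' (0 when never identified).
#'
#' @param runs As in [sweep_parameters()].
#' @param libraries,calib,params As in [identify_components()].
#' @return Numeric vector of scores, one per compound x run.
#' @export
truth_scores <- function(runs, libraries, calib, params = match_params()) {
  pm <- params
  pm$min_match_factor <- 0
  unlist(lapply(runs, function(r) {
    ids <- identify_components(r$components, libraries, calib, pm)
    vapply(r$truth, function(nm) {
      s <- ids$final_score[ids$entry_name == nm]
      if (length(s)) max(s) else 0
    }, numeric(1))
  }), use.names = FALSE)
}

#' Screening detection limit per compound
#'
#' The SDL is the lowest tested concentration level at which the compound was
#' detected in at least `min_rate` of the replicates, requiring every higher
#' tested level to satisfy the rule as well ("the lowest concentration for
#' which detection has been demonstrated"). Compounds for which no level
#' qualifies are reported as not determined (`NA`).
#'
#' @param detections data.frame with columns `compound`, `level` (numeric),
#'   `replicate`, `detected` (logical).
#' @param min_rate Minimum detection fraction (default 0.95).
#' @return data.frame `compound`, `sdl` (`NA` = not determined).
#' @export
compute_sdl <- function(detections, min_rate = 0.95) {
  stopifnot(all(c("compound", "level", "detected") %in% names(detections)))
  out <- lapply(split(detections, detections$compound), function(d) {
    lv <- sort(unique(d$level))
    frac <- vapply(lv, function(l) mean(d$detected[d$level == l]), numeric(1))
    ok <- frac >= min_rate
    # lowest level such that it and all higher levels pass
    pass_from <- rev(cumprod(rev(ok))) > 0
    sdl <- if (any(pass_from)) lv[which(pass_from)[1L]] else NA_real_
    data.frame(compound = d$compound[1L], sdl = sdl)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simple external-standard quantitation and recovery
#'
#' One-point external-standard arithmetic: concentrations are peak areas
#' scaled by the standard's response (`standard_area / standard_conc`), and
#' recoveries are measured concentrations relative to nominal. Provided as a
#' convenience for spike experiments; it performs no calibration-curve
#' fitting or validation.
#'
#' @param areas Numeric peak areas of the analyte in the samples.
#' @param standard_area Peak area of the external standard.
#' @param standard_conc Concentration of the external standard.
#' @param nominal_conc Nominal (spiked) concentration, for recovery.
#' @return data.frame with `conc`, `recovery_pct`, plus attributes
#'   `mean_recovery_pct` and `rsd_pct` across the replicates.
#' @export
quantify_external <- function(areas, standard_area, standard_conc,
                              nominal_conc = NA_real_) {
  stopifnot(standard_area > 0, standard_conc > 0)
  conc <- areas / (standard_area / standard_conc)
  rec <- if (!is.na(nominal_conc)) 100 * conc / nominal_conc else
    rep(NA_real_, length(conc))
  out <- data.frame(conc = conc, recovery_pct = rec)
  attr(out, "mean_recovery_pct") <- mean(rec)
  attr(out, "rsd_pct") <- if (length(conc) > 1L && mean(conc) > 0)
    100 * stats::sd(conc) / mean(conc) else NA_real_
  out
}
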