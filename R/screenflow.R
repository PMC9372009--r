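#' Screening pipeline configuration
#'
#' Bundles the deconvolution and per-library matching parameters with the
#' libraries and alkane calibration. Per-library match parameters may differ
#' (the reference method uses a 20 s retention window for the in-house
#' library and 30 s for the retention-time-locked pesticide library).
#'
#' @param libraries A [spectral_library()] or named list of them.
#' @param calib [alkane_calibration()], or `NULL` when every entry carries a
#'   retention time directly.
#' @param deconv [deconv_params()].
#' @param match A [match_params()] or list parallel to `libraries`.
#' @param blank_exclude Character vector of compound names to drop from
#'   reports (procedural-blank exclusion list).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(libraries, calib = NULL, deconv = deconv_params(),
                          match = match_params(), blank_exclude = character(0)) {
  if (inherits(libraries, "spectral_library"))
    libraries <- list(library = libraries)
  needs_cal <- any(vapply(libraries, function(L)
    any(vapply(L$entries, function(e) !is.na(e$ri) && is.na(e$rt), logical(1))),
    logical(1)))
  if (needs_cal && is.null(calib))
    stop("configuration error: RI-annotated libraries require an alkane calibration")
  structure(list(libraries = libraries, calib = calib, deconv = deconv,
                 match = match, blank_exclude = blank_exclude),
            class = "screen_config")
}

#' Screen one sample end to end
#'
#' Runs the full pipeline: read (when given a path), centroid, extract ion
#' chromatograms, deconvolute, filter, identify against the configured
#' libraries. Stage counts are collected in the returned log.
#'
#' @param run An [ms_run()] or a file path accepted by [read_run()].
#' @param config A [screen_config()].
#' @return List with `identifications` (an `identification_set`),
#'   `components`, and `log` (named counts: scans, components found,
#'   surviving filter, hits).
#' @export
screen_sample <- function(run, config) {
  stopifnot(inherits(config, "screen_config"))
  if (is.character(run)) run <- read_run(run)
  dec <- deconvolve_run(run, config$deconv)
  ids <- identify_components(dec$components, config$libraries, config$calib,
                             config$match)
  if (length(config$blank_exclude))
    ids <- ids[!(ids$entry_name %in% config$blank_exclude), , drop = FALSE]
  list(identifications = ids, components = dec$components,
       log = c(scans = length(run$scans),
               eics = length(dec$eics),
               components_found = length(dec$all_components),
               components_kept = length(dec$components),
               hits = nrow(ids)))
}

#' Deconvolute every sample of an experiment once
#'
#' Deconvolution does not depend on the matching parameters, so sweeps over
#' tolerance, weight factor and cutoff reuse these cached components.
#'
#' @param experiment A `screening_experiment` from
#'   [make_screening_experiment()], or a list of `list(run, truth, level)`.
#' @param deconv [deconv_params()].
#' @return List parallel to the samples, each with `components`, `truth`
#'   (analyte names only), `level`, `replicate`, `sample`.
#' @export
deconvolve_experiment <- function(experiment, deconv = deconv_params()) {
  samples <- if (inherits(experiment, "screening_experiment"))
    experiment$samples else experiment
  lapply(samples, function(s) {
    dec <- deconvolve_run(s$run, deconv)
    tr <- s$truth
    truth_names <- if (is.data.frame(tr)) tr$name[!tr$is_matrix] else tr
    list(components = dec$components, truth = truth_names,
         level = s$level, replicate = s$replicate %||% NA_integer_,
         sample = s$sample %||% NA_character_)
  })
}

#' Run the two-stage optimization protocol on a screening experiment
#'
#' Stage one calibrates, at the highest concentration level, the match-factor
#' cutoff that allows the target false-negative rate for each pure weight
#' factor (the Box-and-Whisker / cutoff-table step). Stage two screens the
#' lowest level with each pure weight factor at its calibrated cutoff and
#' tabulates false positives and negatives (the trade-off figure). Retention
#' penalties are disabled during optimization (`use_rt = FALSE`, the default
#' here mirrors the reference protocol of optimizing on spectral terms only)
#' and can be enabled for final screening.
#'
#' @param experiment A `screening_experiment`, or the output of
#'   [deconvolve_experiment()] (pass `deconvoluted = TRUE`).
#' @param libraries,calib Defaults taken from the experiment.
#' @param pwf_grid Pure weight factors to evaluate.
#' @param target_fn_rate Allowed false-negative fraction for cutoffs.
#' @param params Base [match_params()].
#' @param use_rt If `FALSE`, entries are scored without retention evidence.
#' @param deconv [deconv_params()] (when deconvolution still has to happen).
#' @param deconvoluted Set when `experiment` is already deconvoluted.
#' @return List of class `screening_optimization`: `cutoffs` (data.frame
#'   `pwf`, `cutoff`), `tradeoff` (data.frame per pwf: `fp`, `fn`,
#'   `fn_rate_pct`, `fp_per_sample`), `high_level`, `low_level`.
#' @export
run_experiment <- function(experiment, libraries = NULL, calib = NULL,
                           pwf_grid = c(0, 0.1, 0.25, 0.5, 0.75, 1),
                           target_fn_rate = 0.05, params = match_params(),
                           use_rt = FALSE, deconv = deconv_params(),
                           deconvoluted = FALSE) {
  if (inherits(experiment, "screening_experiment")) {
    libraries <- libraries %||% experiment$library
    calib <- calib %||% experiment$calibration
    decs <- deconvolve_experiment(experiment, deconv)
  } else decs <- experiment
  if (is.null(libraries)) stop("libraries must be supplied")
  if (!use_rt) libraries <- strip_rt_library(libraries)
  levels <- vapply(decs, `[[`, numeric(1), "level")
  hi <- max(levels); lo <- min(levels)
  hi_runs <- decs[levels == hi]
  lo_runs <- decs[levels == lo]
  # pairing/cosine tables are pwf-independent: compute once per run
  hi_tabs <- lapply(hi_runs, function(r)
    component_scores(r$components, libraries, calib, params))
  cutoffs <- vapply(pwf_grid, function(pwf) {
    scores <- unlist(lapply(seq_along(hi_runs), function(i) {
      ids <- select_hits(hi_tabs[[i]], pwf, 0, params$max_hits,
                         params$threshold_on)
      vapply(hi_runs[[i]]$truth, function(nm) {
        s <- ids$final_score[ids$entry_name == nm]
        if (length(s)) max(s) else 0
      }, numeric(1))
    }), use.names = FALSE)
    cutoff_for_fn_rate(scores, target_fn_rate)
  }, numeric(1))
  lo_tabs <- lapply(lo_runs, function(r)
    component_scores(r$components, libraries, calib, params))
  trade <- do.call(rbind, lapply(seq_along(pwf_grid), function(i) {
    tp <- fp <- fn <- 0L
    for (j in seq_along(lo_runs)) {
      ids <- select_hits(lo_tabs[[j]], pwf_grid[i], cutoffs[i],
                         params$max_hits, params$threshold_on)
      ev <- score_detections(ids, lo_runs[[j]]$truth)
      tp <- tp + ev$tp; fp <- fp + ev$fp; fn <- fn + ev$fn
    }
    data.frame(amt_ppm = params$amt_ppm, pwf = pwf_grid[i],
               cutoff = cutoffs[i], tp = tp, fp = fp, fn = fn,
               fn_rate_pct = 100 * fn / (tp + fn),
               fp_per_sample = fp / length(lo_runs),
               n_samples = length(lo_runs))
  }))
  structure(list(cutoffs = data.frame(pwf = pwf_grid, cutoff = cutoffs),
                 tradeoff = trade, high_level = hi, low_level = lo),
            class = "screening_optimization")
}

#' Drop retention annotations from a library
#'
#' Returns a copy whose entries carry neither retention time nor retention
#' index, so identifications are made on spectral terms alone - the setting
#' used while optimizing tolerance, cutoff and pure weight factor.
#'
#' @param libraries A [spectral_library()] or list of them.
#' @return Same shape as the input.
#' @export
strip_rt_library <- function(libraries) {
  one <- function(L) {
    L$entries <- lapply(L$entries, function(e) { e$ri <- NA_real_; e$rt <- NA_real_; e })
    L
  }
  if (inherits(libraries, "spectral_library")) one(libraries)
  else lapply(libraries, one)
}

#' @export
print.screening_optimization <- function(x, ...) {
  cat(sprintf("Two-stage screening optimization (cutoffs at level %g, trade-off at level %g)\n",
              x$high_level, x$low_level))
  cat("Cutoffs (target FN rate at high level):\n")
  print(x$cutoffs, row.names = FALSE)
  cat("Low-level trade-off:\n")
  print(x$tradeoff[c("pwf", "cutoff", "tp", "fp", "fn", "fn_rate_pct",
                     "fp_per_sample")], row.names = FALSE)
  invisible(x)
}

#' Detection matrix of an experiment at fixed screening settings
#'
#' Screens every sample and records, per compound x level x replicate,
#' whether it was identified - the input to [compute_sdl()].
#'
#' @param decs Output of [deconvolve_experiment()].
#' @param libraries,calib,params As in [identify_components()].
#' @return data.frame `compound`, `level`, `replicate`, `detected`.
#' @export
detection_matrix <- function(decs, libraries, calib = NULL,
                             params = match_params()) {
  rows <- lapply(decs, function(d) {
    ids <- identify_components(d$components, libraries, calib, params)
    data.frame(compound = d$truth, level = d$level, replicate = d$replicate,
               detected = d$truth %in% ids$entry_name)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
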