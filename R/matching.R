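#' Library-search parameters
#'
#' Defaults are the optimized screening settings: accurate mass tolerance
#' (AMT) 50 ppm, pure weight factor (PWF) 0.1, minimum m/z 30, minimum match
#' factor 75, a trapezoidal multiplicative retention-time penalty with a 20 s
#' penalty-free window, 20 s search range and maximum penalty 20 (the
#' in-house-library values; a retention-time-locked pesticide library uses
#' 30/30/30), and a single best hit per component.
#'
#' @param amt_ppm Accurate mass tolerance in ppm.
#' @param pwf Pure weight factor in `[0, 1]`: 0 = pure reverse search,
#'   1 = pure forward search.
#' @param min_mz Ions below this m/z are excluded from pairing and scoring.
#' @param min_match_factor Identification cutoff on the 0-100 score.
#' @param rt_range_s Search window: hits with |delta rt| beyond it are
#'   rejected outright (set `soft_penalty = TRUE` to apply the maximum
#'   penalty instead).
#' @param penalty_free_s No penalty within this |delta rt|.
#' @param max_rt_penalty Penalty (score points) reached at `rt_range_s`.
#' @param max_hits Best hits retained per component.
#' @param intensity_power,mz_power Stein-Scott weighting exponents for the
#'   weighted cosine (`w = intensity^0.5 * mz^1.3` by default).
#' @param threshold_on `"final"` applies `min_match_factor` after the
#'   retention penalty (default), `"raw"` before.
#' @param soft_penalty See `rt_range_s`.
#' @return A list of class `match_params`.
#' @export
match_params <- function(amt_ppm = 50, pwf = 0.1, min_mz = 30,
                         min_match_factor = 75, rt_range_s = 20,
                         penalty_free_s = 20, max_rt_penalty = 20,
                         max_hits = 1L, intensity_power = 0.5,
                         mz_power = 1.3, threshold_on = c("final", "raw"),
                         soft_penalty = FALSE) {
  threshold_on <- match.arg(threshold_on)
  stopifnot(pwf >= 0, pwf <= 1, penalty_free_s <= rt_range_s,
            amt_ppm > 0, min_mz >= 0, max_rt_penalty >= 0,
            max_rt_penalty <= 100, max_hits >= 1)
  structure(list(amt_ppm = amt_ppm, pwf = pwf, min_mz = min_mz,
                 min_match_factor = min_match_factor, rt_range_s = rt_range_s,
                 penalty_free_s = penalty_free_s,
                 max_rt_penalty = max_rt_penalty,
                 max_hits = as.integer(max_hits),
                 intensity_power = intensity_power, mz_power = mz_power,
                 threshold_on = threshold_on, soft_penalty = soft_penalty),
            class = "match_params")
}

# One-to-one accurate-mass pairing on plain vectors (both sides already
# filtered to mz >= min_mz and ascending). Candidates within amt_ppm of a
# library ion are ranked by ppm error (ties toward higher query intensity)
# and accepted greedily. Returns integer index vectors into the filtered
# sides plus ppm errors.
pair_vectors <- function(qmz, qint, lmz, amt_ppm) {
  if (!length(qmz) || !length(lmz))
    return(list(li = integer(0), qj = integer(0), ppm = numeric(0)))
  tol <- lmz * amt_ppm * 1e-6
  lo <- findInterval(lmz - tol, qmz) + 1L
  hi <- findInterval(lmz + tol, qmz)
  nc <- pmax(hi - lo + 1L, 0L)
  if (!sum(nc)) return(list(li = integer(0), qj = integer(0), ppm = numeric(0)))
  li <- rep.int(seq_along(lmz), nc)
  qj <- sequence(nc) + rep.int(lo - 1L, nc)
  ppm <- abs(qmz[qj] - lmz[li]) / lmz[li] * 1e6
  o <- order(ppm, -qint[qj])
  li <- li[o]; qj <- qj[o]; ppm <- ppm[o]
  used_l <- logical(length(lmz)); used_q <- logical(length(qmz))
  keep <- logical(length(li))
  for (r in seq_along(li)) {
    if (!used_l[li[r]] && !used_q[qj[r]]) {
      keep[r] <- TRUE; used_l[li[r]] <- TRUE; used_q[qj[r]] <- TRUE
    }
  }
  list(li = li[keep], qj = qj[keep], ppm = ppm[keep])
}

#' Pair query ions with library ions by accurate mass
#'
#' Ions below `min_mz` are removed from both sides. Each library ion is
#' paired with the nearest query ion within `amt_ppm` (ppm computed relative
#' to the library mass). The pairing is one-to-one; conflicts are resolved in
#' favor of the smallest ppm error, ties toward the higher-intensity query
#' ion.
#'
#' @param query A [centroid_spectrum()] (a deconvoluted component spectrum).
#' @param entry A [library_entry()].
#' @param amt_ppm Accurate mass tolerance, ppm.
#' @param min_mz Minimum m/z considered.
#' @return List with `pairs` (data.frame `lib_mz`, `lib_int`, `query_mz`,
#'   `query_int`, `ppm_error`), `unmatched_query` and `unmatched_lib`
#'   (data.frames `mz`, `intensity`).
#' @export
match_ions <- function(query, entry, amt_ppm = 50, min_mz = 30) {
  qk <- query$mz >= min_mz
  qmz <- query$mz[qk]; qint <- query$intensity[qk]
  lk <- entry$spectrum$mz >= min_mz
  lmz <- entry$spectrum$mz[lk]; lint <- entry$spectrum$rel_intensity[lk]
  p <- pair_vectors(qmz, qint, lmz, amt_ppm)
  um_q <- setdiff(seq_along(qmz), p$qj)
  um_l <- setdiff(seq_along(lmz), p$li)
  list(pairs = data.frame(lib_mz = lmz[p$li], lib_int = lint[p$li],
                          query_mz = qmz[p$qj], query_int = qint[p$qj],
                          ppm_error = p$ppm),
       unmatched_query = data.frame(mz = qmz[um_q], intensity = qint[um_q]),
       unmatched_lib = data.frame(mz = lmz[um_l], intensity = lint[um_l]))
}

#' Weighted forward/reverse match factor
#'
#' Both directions use the Stein-Scott weighted cosine with weights
#' `w = intensity^p * mz^q` (defaults p = 0.5, q = 1.3). The reverse score R
#' is the cosine restricted to the library's ions (query-only ions are
#' ignored); the forward score F is the cosine over the union of both ion
#' sets, so unmatched ions on either side contribute a zero-valued partner.
#' The composite score is the pure-weight-factor mixture
#' `100 * (pwf * F + (1 - pwf) * R)`: 0 is a pure reverse search, 1 a pure
#' forward search, values between a weighted combination.
#'
#' @param pairing Result of [match_ions()].
#' @param pwf Pure weight factor in `[0, 1]`.
#' @param intensity_power,mz_power Weighting exponents.
#' @return List with `score` (0-100), `forward`, `reverse` (cosines in
#'   `[0, 1]`).
#' @export
match_factor <- function(pairing, pwf = 0.1, intensity_power = 0.5,
                         mz_power = 1.3) {
  w <- function(mz, int) int^intensity_power * mz^mz_power
  p <- pairing$pairs
  if (nrow(p) == 0L) return(list(score = 0, forward = 0, reverse = 0))
  wl_p <- w(p$lib_mz, p$lib_int)
  wq_p <- w(p$query_mz, p$query_int)
  wl_u <- w(pairing$unmatched_lib$mz, pairing$unmatched_lib$intensity)
  wq_u <- w(pairing$unmatched_query$mz, pairing$unmatched_query$intensity)
  dot <- sum(wl_p * wq_p)
  norm_l <- sqrt(sum(wl_p^2) + sum(wl_u^2))
  norm_q_paired <- sqrt(sum(wq_p^2))
  norm_q_all <- sqrt(sum(wq_p^2) + sum(wq_u^2))
  reverse <- if (norm_l * norm_q_paired > 0) dot / (norm_l * norm_q_paired) else 0
  forward <- if (norm_l * norm_q_all > 0) dot / (norm_l * norm_q_all) else 0
  list(score = 100 * (pwf * forward + (1 - pwf) * reverse),
       forward = forward, reverse = reverse)
}

#' Trapezoidal retention-time penalty
#'
#' Multiplicative score penalty: no penalty while
#' `|delta rt| <= penalty_free_s`; from there the penalty ramps linearly to
#' `max_rt_penalty` score points at `rt_range_s`; beyond `rt_range_s` the hit
#' is rejected (multiplier `NA`), or held at the maximum penalty when
#' `params$soft_penalty` is set. With the in-house settings
#' (penalty-free 20 s, range 20 s) the ramp is empty: hits are unpenalized
#' inside 20 s and rejected outside.
#'
#' @param delta_rt_s Absolute observed-minus-expected retention time, s.
#' @param params [match_params()].
#' @return Multiplier in `(0, 1]`, or `NA_real_` for a rejected hit.
#' @export
rt_penalty <- function(delta_rt_s, params = match_params()) {
  d <- abs(delta_rt_s)
  if (d <= params$penalty_free_s) return(1)
  if (d > params$rt_range_s)
    return(if (params$soft_penalty) (100 - params$max_rt_penalty) / 100
           else NA_real_)
  ramp <- (d - params$penalty_free_s) /
    (params$rt_range_s - params$penalty_free_s)
  (100 - ramp * params$max_rt_penalty) / 100
}

#' Forward/reverse score table of components against libraries
#'
#' The pwf-independent core of the library search: for every component x
#' entry pair, the forward and reverse weighted cosines, the retention-time
#' penalty multiplier (`NA` = outside the search window) and pairing
#' diagnostics. [identify_components()] and the parameter sweeps derive
#' final scores from this table, so a sweep over pure weight factors and
#' cutoffs costs arithmetic only.
#'
#' @param components List of components.
#' @param libraries A [spectral_library()] or named list of them.
#' @param calib [alkane_calibration()] or `NULL`.
#' @param params A [match_params()] or list parallel to `libraries`.
#' @return data.frame with one row per scored pair: `component_id`,
#'   `component_rt`, `component_ri`, `entry_name`, `library`, `forward`,
#'   `reverse`, `penalty_multiplier`, `matched_ions`,
#'   `mean_abs_mass_error_ppm`, `delta_rt_s`, `rt_evidence`.
#' @export
component_scores <- function(components, libraries, calib = NULL,
                             params = match_params()) {
  if (inherits(libraries, "spectral_library"))
    libraries <- list(library = libraries)
  if (inherits(params, "match_params"))
    params <- rep(list(params), length(libraries))
  stopifnot(length(params) == length(libraries))
  lib_ids <- names(libraries) %||% as.character(seq_along(libraries))
  needs_cal <- any(vapply(libraries, function(L)
    any(vapply(L$entries, function(e) !is.na(e$ri) && is.na(e$rt), logical(1))),
    logical(1)))
  if (needs_cal && is.null(calib))
    stop("libraries carry retention indices but no alkane calibration was given")
  n_comp <- length(components)
  # per-component filtered query vectors and weight norms
  comp_rt <- vapply(components, `[[`, numeric(1), "apex_rt")
  comp_ri <- if (!is.null(calib)) as.numeric(rt_to_ri(comp_rt, calib))
    else rep(NA_real_, n_comp)
  out <- list()
  for (L in seq_along(libraries)) {
    pm <- params[[L]]
    wfun <- function(mz, int) int^pm$intensity_power * mz^pm$mz_power
    qs <- lapply(components, function(comp) {
      spec <- component_spectrum(comp)
      k <- spec$mz >= pm$min_mz
      mz <- spec$mz[k]; int <- spec$intensity[k]
      wq <- wfun(mz, int)
      list(mz = mz, int = int, wq = wq, norm2 = sum(wq^2))
    })
    entries <- libraries[[L]]$entries
    es <- lapply(entries, function(e) {
      k <- e$spectrum$mz >= pm$min_mz
      mz <- e$spectrum$mz[k]; int <- e$spectrum$rel_intensity[k]
      wl <- wfun(mz, int)
      exp_rt <- if (!is.na(e$ri) && !is.null(calib))
        as.numeric(ri_to_rt(e$ri, calib))
      else if (!is.na(e$rt)) e$rt else NA_real_
      list(mz = mz, int = int, wl = wl, norm2 = sum(wl^2), exp_rt = exp_rt,
           name = e$name)
    })
    for (ci in seq_len(n_comp)) {
      q <- qs[[ci]]
      if (!length(q$mz)) next
      for (ei in seq_along(es)) {
        e <- es[[ei]]
        if (!length(e$mz)) next
        if (is.na(e$exp_rt)) {
          mult <- 1; drt <- NA_real_; evid <- "no-RT evidence"
        } else {
          drt <- comp_rt[ci] - e$exp_rt
          mult <- rt_penalty(abs(drt), pm)
          evid <- "rt"
          if (is.na(mult)) next
        }
        p <- pair_vectors(q$mz, q$int, e$mz, pm$amt_ppm)
        if (!length(p$li)) next
        dot <- sum(e$wl[p$li] * q$wq[p$qj])
        nl <- sqrt(e$norm2)
        rev_ <- dot / (nl * sqrt(sum(q$wq[p$qj]^2)))
        fwd <- dot / (nl * sqrt(q$norm2))
        out[[length(out) + 1L]] <- list(
          component_id = ci, component_rt = comp_rt[ci],
          component_ri = comp_ri[ci], entry_name = e$name,
          library = lib_ids[L], forward = fwd, reverse = rev_,
          penalty_multiplier = mult, matched_ions = length(p$li),
          mean_abs_mass_error_ppm = mean(p$ppm), delta_rt_s = drt,
          rt_evidence = evid)
      }
    }
  }
  if (!length(out)) return(empty_score_table())
  data.frame(
    component_id = vapply(out, `[[`, numeric(1), "component_id"),
    component_rt = vapply(out, `[[`, numeric(1), "component_rt"),
    component_ri = vapply(out, `[[`, numeric(1), "component_ri"),
    entry_name = vapply(out, `[[`, character(1), "entry_name"),
    library = vapply(out, `[[`, character(1), "library"),
    forward = vapply(out, `[[`, numeric(1), "forward"),
    reverse = vapply(out, `[[`, numeric(1), "reverse"),
    penalty_multiplier = vapply(out, `[[`, numeric(1), "penalty_multiplier"),
    matched_ions = vapply(out, `[[`, numeric(1), "matched_ions"),
    mean_abs_mass_error_ppm = vapply(out, `[[`, numeric(1),
                                     "mean_abs_mass_error_ppm"),
    delta_rt_s = vapply(out, `[[`, numeric(1), "delta_rt_s"),
    rt_evidence = vapply(out, `[[`, character(1), "rt_evidence"),
    stringsAsFactors = FALSE)
}

empty_score_table <- function() {
  data.frame(component_id = numeric(0), component_rt = numeric(0),
             component_ri = numeric(0), entry_name = character(0),
             library = character(0), forward = numeric(0),
             reverse = numeric(0), penalty_multiplier = numeric(0),
             matched_ions = numeric(0), mean_abs_mass_error_ppm = numeric(0),
             delta_rt_s = numeric(0), rt_evidence = character(0),
             stringsAsFactors = FALSE)
}

# final scores + hit selection from a score table (internal fast path)
select_hits <- function(tab, pwf, min_match_factor, max_hits = 1L,
                        threshold_on = "final") {
  if (!nrow(tab)) return(cbind(tab, raw_match = numeric(0),
                               final_score = numeric(0)))
  raw <- 100 * (pwf * tab$forward + (1 - pwf) * tab$reverse)
  final <- raw * tab$penalty_multiplier
  keep <- if (threshold_on == "raw") raw >= min_match_factor
    else final >= min_match_factor
  tab <- tab[keep, , drop = FALSE]
  raw <- raw[keep]; final <- final[keep]
  if (!nrow(tab)) return(cbind(tab, raw_match = numeric(0),
                               final_score = numeric(0)))
  tab$raw_match <- raw
  tab$final_score <- final
  o <- order(tab$component_id, -tab$final_score, -tab$raw_match,
             abs(tab$delta_rt_s), tab$entry_name, method = "radix")
  tab <- tab[o, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(tab)), tab$component_id,
                     FUN = seq_along)
  tab <- tab[rank <= max_hits, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Identify deconvoluted components against spectral libraries
#'
#' Every component spectrum is scored against every entry of every library
#' (accurate-mass ion pairing, PWF-weighted forward/reverse match factor,
#' multiplicative trapezoidal retention penalty). Hits below
#' `min_match_factor` are dropped and at most `max_hits` best hits are kept
#' per component (ties broken by higher raw match, then smaller |delta rt|,
#' then name). The expected retention time of an RI-annotated entry comes
#' from the sample's own alkane calibration; entries carrying only `rt` use
#' it directly; entries with neither are scored without retention evidence
#' and flagged.
#'
#' @param components List of components from [deconvolve_run()].
#' @param libraries A [spectral_library()] or named list of them.
#' @param calib [alkane_calibration()]; required when any library entry
#'   carries only an RI.
#' @param params A [match_params()] or list of them parallel to `libraries`
#'   (per-library windows, e.g. 20 s in-house vs 30 s pesticide).
#' @return data.frame of class `identification_set`: `component_id`,
#'   `component_rt`, `component_ri`, `entry_name`, `library`, `raw_match`,
#'   `penalty_multiplier`, `final_score`, `matched_ions`,
#'   `mean_abs_mass_error_ppm`, `delta_rt_s`, `rt_evidence`.
#' @export
identify_components <- function(components, libraries, calib = NULL,
                                params = match_params()) {
  single <- inherits(params, "match_params")
  tab <- component_scores(components, libraries, calib, params)
  pm <- if (single) params else params[[1L]]
  if (!single) {
    # per-library pwf/cutoff may differ: select within each library, merge
    libsplit <- split(seq_len(nrow(tab)), tab$library)
    lib_ids <- names(if (inherits(libraries, "spectral_library"))
      list(library = libraries) else libraries) %||%
      as.character(seq_along(params))
    parts <- lapply(seq_along(params), function(L) {
      rows <- libsplit[[lib_ids[L]]]
      if (is.null(rows)) return(NULL)
      p <- params[[L]]
      select_hits(tab[rows, , drop = FALSE], p$pwf, p$min_match_factor,
                  max_hits = nrow(tab), threshold_on = p$threshold_on)
    })
    merged <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    res <- select_hits_premixed(merged, min(vapply(params, `[[`, integer(1),
                                                   "max_hits")))
  } else {
    res <- select_hits(tab, pm$pwf, pm$min_match_factor, pm$max_hits,
                       pm$threshold_on)
  }
  res <- res[c("component_id", "component_rt", "component_ri", "entry_name",
               "library", "raw_match", "penalty_multiplier", "final_score",
               "matched_ions", "mean_abs_mass_error_ppm", "delta_rt_s",
               "rt_evidence")]
  class(res) <- c("identification_set", "data.frame")
  res
}

# best max_hits rows per component when raw/final are already computed
select_hits_premixed <- function(tab, max_hits) {
  if (is.null(tab) || !nrow(tab)) {
    tab <- cbind(empty_score_table(), raw_match = numeric(0),
                 final_score = numeric(0))
    return(tab)
  }
  o <- order(tab$component_id, -tab$final_score, -tab$raw_match,
             abs(tab$delta_rt_s), tab$entry_name, method = "radix")
  tab <- tab[o, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(tab)), tab$component_id, FUN = seq_along)
  tab <- tab[rank <= max_hits, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write an identification report CSV
#'
#' @param ids An `identification_set` from [identify_components()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_identifications_csv <- function(ids, path) {
  utils::write.csv(as.data.frame(ids), path, row.names = FALSE)
  invisible(path)
}
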