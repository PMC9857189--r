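#' Normalization configuration
#'
#' Settings for LOESS GC-bias correction. Sequencing depth in shallow WGS
#' depends smoothly on the local GC fraction of each bin; the dependence is
#' estimated per sample by LOESS regression of raw depth on GC and removed
#' multiplicatively (`ratio` mode, the default, because coverage bias acts as
#' a multiplicative efficiency) or additively (`subtract`, kept for
#' comparison). Bins with extreme GC are unreliable at shallow depth and are
#' flagged rather than corrected; flagged features propagate as missing
#' through Z-scoring.
#'
#' @param loess_span LOESS span in (0, 1]; default 0.75.
#' @param degree local polynomial degree (1 or 2); default 2.
#' @param correction_mode `"ratio"` or `"subtract"`.
#' @param min_gc,max_gc GC eligibility window; default \[0.28, 0.68\].
#' @param depth_floor bins at or below this raw depth are excluded from the
#'   fit; default 0.
#' @return a `norm_config` list.
#' @export
norm_config <- function(loess_span = 0.75, degree = 2,
                        correction_mode = c("ratio", "subtract"),
                        min_gc = 0.28, max_gc = 0.68, depth_floor = 0) {
  correction_mode <- match.arg(correction_mode)
  if (loess_span <= 0 || loess_span > 1) stop_giscan("loess_span must be in (0, 1]")
  if (min_gc >= max_gc) stop_giscan("min_gc must be < max_gc")
  structure(list(loess_span = loess_span, degree = degree,
                 correction_mode = correction_mode, min_gc = min_gc,
                 max_gc = max_gc, depth_floor = depth_floor),
            class = "norm_config")
}

#' LOESS GC-bias correction of a depth profile
#'
#' Fits `raw_depth ~ loess(gc)` on the eligible **bins** of the profile
#' (GC inside the config window, depth above the floor) and corrects every
#' feature — bins and gene bodies alike — by evaluating the fitted curve at
#' the feature's GC. Gene bodies are never part of the fit: a 33-gene panel
#' is far too few points for a stable smooth, so genes borrow the bin-level
#' curve, which is estimated from thousands of bins of the same library.
#'
#' In `ratio` mode the corrected depth is `raw / fitted`, rescaled so the
#' median over eligible bins exactly equals the median raw depth over the
#' same bins — GC correction should reshape a profile, not change its overall
#' depth. Features whose GC falls outside the window (or outside the fitted
#' GC range) are flagged `gc_out_of_range` with `norm_depth = NA`.
#'
#' If all eligible bins share a single GC value no bias is estimable; the
#' profile is returned unchanged with a warning.
#'
#' @param profile a `depth_profile`.
#' @param cfg a [norm_config()].
#' @return the profile with `norm_depth` and `flag` filled in.
#' @export
loess_gc_normalize <- function(profile, cfg = norm_config()) {
  stopifnot(inherits(profile, "depth_profile"))
  gc <- profile$gc
  raw <- profile$raw_depth
  is_bin <- profile$feature_type == "bin"
  in_window <- !is.na(gc) & gc >= cfg$min_gc & gc <= cfg$max_gc
  eligible <- is_bin & in_window & !is.na(raw) & raw > cfg$depth_floor
  if (sum(eligible) < 50)
    stop_giscan(paste0("only %d eligible bins for the GC fit (need >= 50); ",
                       "provide more bins or widen the GC window"),
                sum(eligible))

  out <- profile
  out$flag <- ifelse(in_window, NA_character_, "gc_out_of_range")

  gc_e <- gc[eligible]
  if (length(unique(gc_e)) == 1) {
    warn_giscan("all eligible bins share GC=%.3f; no bias estimable, depth left uncorrected",
                gc_e[1])
    out$norm_depth <- ifelse(is.na(out$flag), raw, NA_real_)
    return(out)
  }

  fit <- stats::loess(raw[eligible] ~ gc_e, span = cfg$loess_span,
                      degree = cfg$degree)
  fitted_all <- rep(NA_real_, nrow(profile))
  idx <- which(!is.na(gc) & is.na(out$flag))
  fitted_all[idx] <- as.numeric(predict(fit, data.frame(gc_e = gc[idx])))
  bad_fit <- idx[!is.finite(fitted_all[idx]) | fitted_all[idx] <= 0]
  if (length(bad_fit) > 0) out$flag[bad_fit] <- "unstable_fit"

  ok <- is.na(out$flag) & is.finite(fitted_all) & fitted_all > 0
  ref <- eligible & ok  # eligible bins that survived the fit anchor the median
  norm <- rep(NA_real_, nrow(profile))
  med_raw <- median(raw[ref])
  if (cfg$correction_mode == "ratio") {
    ratio <- raw / fitted_all
    scale <- med_raw / median(ratio[ref])
    norm[ok] <- ratio[ok] * scale
  } else {
    resid <- raw - fitted_all
    shift <- med_raw - median(resid[ref])
    norm[ok] <- pmax(0, resid[ok] + shift)
  }
  out$norm_depth <- norm
  out
}
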