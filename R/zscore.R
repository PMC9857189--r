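#' Build the healthy-control reference model
#'
#' Per-feature mean and standard deviation of GC-normalized depth across a
#' cohort of healthy controls (20 subjects in the motivating study). The SD
#' uses the unbiased n-1 denominator and is floored at
#' `max(1e-6, sigma_floor_frac * mu)`: shallow-depth counting noise implies a
#' coefficient-of-variation floor, and an unfloored zero SD would make every
#' downstream Z infinite. Features that are missing (flagged) in one or more
#' controls keep a reference as long as at least two controls observe them.
#'
#' @param control_profiles list of normalized `depth_profile`s with identical
#'   feature sets in identical order.
#' @param sigma_floor_frac floor on sigma as a fraction of mu; default 0.05.
#' @return a `reference_model` list: `feature_ids`, `feature_type`, `chrom`,
#'   `mu`, `sigma`, `n_controls`, `sigma_floor_frac`.
#' @export
build_reference <- function(control_profiles, sigma_floor_frac = 0.05) {
  if (length(control_profiles) < 2)
    stop_giscan("need at least 2 control profiles, got %d",
                length(control_profiles))
  ids <- control_profiles[[1]]$feature_id
  for (p in control_profiles[-1]) {
    if (!identical(p$feature_id, ids))
      stop_giscan("control profiles have mismatched feature sets (sample '%s')",
                  attr(p, "sample_id"))
  }
  depth_mat <- vapply(control_profiles, function(p) p$norm_depth,
                      numeric(length(ids)))
  if (all(is.na(depth_mat)))
    stop_giscan("control profiles are not normalized; run loess_gc_normalize first")
  n_obs <- rowSums(!is.na(depth_mat))
  mu <- rowMeans(depth_mat, na.rm = TRUE)
  sigma <- apply(depth_mat, 1, sd, na.rm = TRUE)
  mu[n_obs < 2] <- NA_real_
  sigma[n_obs < 2] <- NA_real_
  floor_at <- pmax(1e-6, sigma_floor_frac * mu)
  sigma <- pmax(sigma, floor_at)
  structure(list(feature_ids = ids,
                 feature_type = control_profiles[[1]]$feature_type,
                 chrom = control_profiles[[1]]$chrom,
                 mu = as.numeric(mu), sigma = as.numeric(sigma),
                 n_controls = length(control_profiles),
                 sigma_floor_frac = sigma_floor_frac),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference_model: %d features from %d controls (sigma floor %.0f%% of mu)\n",
              length(x$feature_ids), x$n_controls, 100 * x$sigma_floor_frac))
  invisible(x)
}

#' Depth Z-scores against the control reference
#'
#' `z = (norm_depth - mu) / sigma` per feature. Features flagged during
#' normalization, or lacking a reference, get `NA` and are excluded from
#' downstream calling and Gi scoring.
#'
#' @param profile a normalized `depth_profile`.
#' @param ref a [build_reference()] model with the same feature set.
#' @return a `z_profile` data frame: `feature_id`, `feature_type`, `chrom`,
#'   `z`, with a `sample_id` attribute.
#' @export
zscore <- function(profile, ref) {
  if (!identical(profile$feature_id, ref$feature_ids))
    stop_giscan("profile '%s' and reference have mismatched feature sets",
                attr(profile, "sample_id"))
  if (all(is.na(profile$norm_depth)))
    stop_giscan("profile '%s' is not normalized", attr(profile, "sample_id"))
  z <- (profile$norm_depth - ref$mu) / ref$sigma
  z[!is.na(profile$flag)] <- NA_real_
  out <- data.frame(feature_id = profile$feature_id,
                    feature_type = profile$feature_type,
                    chrom = profile$chrom,
                    z = as.numeric(z), stringsAsFactors = FALSE)
  attr(out, "sample_id") <- attr(profile, "sample_id")
  class(out) <- c("z_profile", "data.frame")
  out
}

#' Threshold copy-number call from a Z-score
#'
#' A Z-score exceeding +2 is called an amplification and one below -2 a
#' deletion; the thresholds are strict, so Z = 2 exactly is `NEUTRAL`.
#' Missing Z-scores return `NA`.
#'
#' @param z numeric vector of Z-scores.
#' @param z_amp,z_del call thresholds (defaults +2 / -2).
#' @return character vector in `{"AMP", "DEL", "NEUTRAL", NA}`.
#' @examples
#' call_cnv(c(2.5, -2.5, 2, -2, 0))  # AMP DEL NEUTRAL NEUTRAL NEUTRAL
#' @export
call_cnv <- function(z, z_amp = 2, z_del = -2) {
  out <- rep(NA_character_, length(z))
  out[!is.na(z)] <- "NEUTRAL"
  out[!is.na(z) & z > z_amp] <- "AMP"
  out[!is.na(z) & z < z_del] <- "DEL"
  out
}

#' Directional 0/1 grouping against the panel's expected CNV type
#'
#' Each panel gene has an expected alteration direction. For an `AMP` gene a
#' patient is grouped 1 when z > 2 (and 0 otherwise, including strong
#' deletions — only the panel direction counts as an event); for a `DEL` gene,
#' grouped 1 when z < -2. Missing Z maps to 0.
#'
#' @param z numeric vector of gene Z-scores.
#' @param direction matching character vector of `"AMP"`/`"DEL"` (recycled if
#'   scalar).
#' @param z_amp,z_del thresholds as in [call_cnv()].
#' @return integer vector of 0/1 group labels.
#' @export
group_by_direction <- function(z, direction, z_amp = 2, z_del = -2) {
  if (length(direction) == 1) direction <- rep(direction, length(z))
  if (length(direction) != length(z))
    stop_giscan("z and direction lengths differ")
  if (!all(direction %in% c("AMP", "DEL")))
    stop_giscan("direction must be 'AMP' or 'DEL'")
  grp <- integer(length(z))
  amp <- direction == "AMP"
  grp[amp & !is.na(z) & z > z_amp] <- 1L
  grp[!amp & !is.na(z) & z < z_del] <- 1L
  grp
}

#' Per-gene CNV call table for one sample
#'
#' Combines [call_cnv()] and [group_by_direction()] over the gene features of
#' a Z-profile.
#'
#' @param zp a `z_profile` containing gene features.
#' @param panel the `gene_panel` (defines the expected direction per gene).
#' @param z_amp,z_del thresholds.
#' @return data frame: `sample_id`, `gene`, `direction`, `z`, `call`,
#'   `group`, `flagged`.
#' @export
cnv_call_table <- function(zp, panel, z_amp = 2, z_del = -2) {
  genes <- zp[zp$feature_type == "gene", ]
  if (nrow(genes) == 0) stop_giscan("z_profile carries no gene features")
  m <- match(panel$gene, genes$feature_id)
  if (any(is.na(m)))
    stop_giscan("panel genes missing from z_profile: %s",
                paste(panel$gene[is.na(m)], collapse = ", "))
  z <- genes$z[m]
  data.frame(sample_id = attr(zp, "sample_id"),
             gene = panel$gene,
             direction = panel$direction,
             z = z,
             call = call_cnv(z, z_amp, z_del),
             group = group_by_direction(z, panel$direction, z_amp, z_del),
             flagged = is.na(z),
             stringsAsFactors = FALSE)
}
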