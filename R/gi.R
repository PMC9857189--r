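#' Genome-wide instability (Gi) score
#'
#' The Gi score summarises chromosomal instability as the sum of absolute
#' depth Z-scores over a feature set: `Gi = sum(|z|)`. By default it is taken
#' over autosomal genome bins (sex chromosomes excluded — the contrast of
#' interest is somatic instability, and X depth depends on cohort sex
#' composition); `features = "gene"` restricts to the gene panel and
#' `"all"` uses every feature. Missing (flagged) Z-scores are skipped and do
#' not contribute.
#'
#' @param zp a `z_profile`.
#' @param features `"bin"` (default), `"gene"`, or `"all"`.
#' @param include_sex_chroms include chrX/chrY bins? Default `FALSE`.
#' @return a `gi_score` list: `sample_id`, `gi`, `n_features`.
#' @examples
#' # a profile with z = (2, -3, 0.5) has Gi = 5.5
#' @export
gi_score <- function(zp, features = c("bin", "gene", "all"),
                     include_sex_chroms = FALSE) {
  features <- match.arg(features)
  keep <- if (features == "all") rep(TRUE, nrow(zp)) else zp$feature_type == features
  if (!include_sex_chroms)
    keep <- keep & !zp$chrom %in% c("chrX", "chrY", "X", "Y")
  z <- zp$z[keep]
  z <- z[!is.na(z)]
  if (length(z) == 0)
    stop_giscan("no non-missing features available for the Gi score of '%s'",
                attr(zp, "sample_id"))
  structure(list(sample_id = attr(zp, "sample_id"),
                 gi = sum(abs(z)), n_features = length(z)),
            class = "gi_score")
}

#' @export
print.gi_score <- function(x, ...) {
  cat(sprintf("Gi(%s) = %.2f over %d features\n", x$sample_id, x$gi,
              x$n_features))
  invisible(x)
}

gi_values <- function(scores) {
  vapply(scores, function(s) if (inherits(s, "gi_score")) s$gi else as.numeric(s),
         numeric(1))
}

#' Compare Gi scores between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test, the test used to compare
#' instability scores between patients and healthy subjects. The exact null
#' distribution is used for combined n <= 20 without ties; otherwise the
#' normal approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors of Gi scores (or lists of
#'   `gi_score` objects). Each must have length >= 2.
#' @return list: `statistic` (Mann-Whitney U for group_a), `p` (two-sided),
#'   `method`.
#' @export
compare_gi <- function(group_a, group_b) {
  a <- gi_values(group_a)
  b <- gi_values(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop_giscan("each group needs >= 2 values")
  if (length(unique(c(a, b))) == 1) {
    warn_giscan("all Gi values tied across both groups; p = 1")
    return(list(statistic = length(a) * length(b) / 2, p = 1,
                method = "degenerate (all tied)"))
  }
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b)) <= 20 && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  list(statistic = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Z-score concordance under in-silico downsampling
#'
#' Emulates the downsampling experiment used to show that shallower
#' sequencing preserves gene-level Z-scores: per-feature read counts are
#' binomially thinned to `target_fraction`, rescaled back to the original
#' coverage scale, re-normalized with the same LOESS configuration, and
#' re-scored against the same control reference. Returns the Pearson
#' correlation between the full and thinned gene Z-scores.
#'
#' Thinning operates on approximate read counts reconstructed as
#' `depth * feature_length / read_length`.
#'
#' @param profile a `depth_profile` with raw depths (bins + genes).
#' @param target_fraction fraction of reads to keep, in (0, 1].
#' @param ref the control `reference_model`.
#' @param seed RNG seed for the binomial thinning.
#' @param cfg [norm_config()] used for both normalizations.
#' @param read_length nominal read length in bp; default 100.
#' @return list: `r` (Pearson correlation over gene features), `z_full`,
#'   `z_thinned`, `thinned_profile`.
#' @export
downsample_concordance <- function(profile, target_fraction, ref, seed,
                                   cfg = norm_config(), read_length = 100) {
  if (target_fraction <= 0 || target_fraction > 1)
    stop_giscan("target_fraction must be in (0, 1]")
  norm_full <- loess_gc_normalize(profile, cfg)
  z_full <- zscore(norm_full, ref)

  thinned <- profile
  if (target_fraction < 1) {
    len <- profile$end - profile$start
    counts <- round(profile$raw_depth * len / read_length)
    kept <- with_seed(seed, rbinom(length(counts), size = counts,
                                   prob = target_fraction))
    # rescale back to the original coverage so the control reference applies
    thinned$raw_depth <- kept * read_length / len / target_fraction
  }
  thinned <- depth_profile(thinned[setdiff(names(thinned), c("norm_depth", "flag"))],
                           sample_id = paste0(attr(profile, "sample_id"), "_thin"),
                           total_reads = attr(profile, "total_reads") * target_fraction)
  norm_thin <- loess_gc_normalize(thinned, cfg)
  z_thin <- zscore(norm_thin, ref)

  g <- z_full$feature_type == "gene"
  zf <- z_full$z[g]
  zt <- z_thin$z[g]
  okpair <- !is.na(zf) & !is.na(zt)
  if (sum(okpair) < 3)
    stop_giscan("fewer than 3 gene features with Z in both profiles")
  list(r = stats::cor(zf[okpair], zt[okpair], method = "pearson"),
       z_full = zf, z_thinned = zt, thinned_profile = norm_thin)
}
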