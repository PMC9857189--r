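# Hand-rolled brute-force oracles, independent of the package implementation.

# product-limit estimator by direct risk-set counting
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(0)
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv <- c(surv, s)
  }
  list(times = ut, survival = surv)
}

# two-group log-rank by direct O-E/V summation over event times
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  list(chi_square = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# exact two-sided rank-sum p by enumerating all C(n+m, n) group assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n <- length(a)
  W_obs <- sum(r[seq_len(n)])
  Ws <- apply(utils::combn(length(pooled), n), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
}

oracle_gi <- function(z) sum(abs(z[!is.na(z)]))

# ---- small builders ---------------------------------------------------------

# depth profile over n synthetic bins (+ optional gene features)
toy_profile <- function(depth, gc = NULL, sample_id = "toy",
                        feature_type = "bin") {
  n <- length(depth)
  if (is.null(gc)) gc <- rep(0.45, n)
  depth_profile(data.frame(
    feature_id = if (feature_type == "bin") sprintf("bin_chrT_%d", (seq_len(n) - 1) * 100000)
                 else sprintf("G%02d", seq_len(n)),
    feature_type = feature_type, chrom = "chrT",
    start = (seq_len(n) - 1) * 1e5, end = seq_len(n) * 1e5,
    gc = gc, raw_depth = depth, stringsAsFactors = FALSE), sample_id)
}

# z_profile with given z values (bin features on chrT unless stated)
toy_zprofile <- function(z, sample_id = "toy", feature_type = "bin",
                         chrom = "chrT") {
  out <- data.frame(
    feature_id = paste0("f", seq_along(z)), feature_type = feature_type,
    chrom = chrom, z = z, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("z_profile", "data.frame")
  out
}

# reference built from explicit control depth matrix (features x controls)
toy_reference <- function(depth_mat, gc = NULL, feature_type = "bin",
                          ids = NULL) {
  profs <- lapply(seq_len(ncol(depth_mat)), function(j) {
    p <- toy_profile(depth_mat[, j], gc = gc, sample_id = paste0("c", j),
                     feature_type = feature_type)
    if (!is.null(ids)) p$feature_id <- ids
    p$norm_depth <- p$raw_depth  # already on a common scale
    p
  })
  build_reference(profs)
}

# GC-rich beta draws resembling 100 kb human bins
toy_gc <- function(n) rbeta(n, 25.2, 34.8)

# minimal clinical table for n patients
toy_clinical <- function(n, dfs_months, dfs_event, os_months = NULL,
                         os_event = NULL, ca125 = NULL) {
  validate_clinical_tbl(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    ca125 = ca125 %||% rep(100, n),
    figo_stage = rep("III", n), histology = rep("HGSC", n),
    dfs_months = dfs_months, dfs_event = dfs_event,
    os_months = os_months %||% dfs_months,
    os_event = os_event %||% dfs_event,
    brca_status = rep("wild_type", n), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# route through the package validator without relying on the internal name
validate_clinical_tbl <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  on.exit(unlink(path))
  read_clinical(path)
}
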