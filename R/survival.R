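#' Classify a recurrence as relapse or progression
#'
#' Disease recurring within six months of surgery (inclusive) is progression;
#' recurrence after more than six months is relapse.
#'
#' @param months_to_recurrence positive time(s) in months.
#' @return character vector in `{"relapse", "progression"}`.
#' @export
classify_recurrence <- function(months_to_recurrence) {
  if (any(!is.finite(months_to_recurrence) | months_to_recurrence <= 0))
    stop_giscan("months_to_recurrence must be positive")
  ifelse(months_to_recurrence <= 6, "progression", "relapse")
}

as_outcomes <- function(outcomes) {
  if (!all(c("time", "event") %in% names(outcomes)))
    stop_giscan("outcomes need 'time' and 'event' columns")
  if (any(is.na(outcomes$time)) || any(outcomes$time < 0))
    stop_giscan("outcome times must be nonnegative and observed")
  if (!all(outcomes$event %in% c(0, 1)))
    stop_giscan("outcome events must be 0/1")
  outcomes
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator; at tied times events precede censoring,
#' so subjects censored at t remain in the risk set for events at t.
#'
#' @param outcomes data frame with `time` (months) and `event` (1 = event,
#'   0 = censored) columns.
#' @param endpoint label carried through (`"DFS"` or `"OS"`).
#' @return a `km_curve` list: `times` (ordered event times), `survival`
#'   (step values), `at_risk`, `n`, `endpoint`. `survival_at(curve, t)` gives
#'   S(t) for any t, with S(0) = 1.
#' @export
km_estimate <- function(outcomes, endpoint = "DFS") {
  outcomes <- as_outcomes(outcomes)
  if (nrow(outcomes) == 0) stop_giscan("km_estimate needs >= 1 outcome")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = outcomes, conf.type = "none")
  ev <- sf$n.event > 0
  structure(list(times = sf$time[ev], survival = sf$surv[ev],
                 at_risk = sf$n.risk[ev], n = nrow(outcomes),
                 endpoint = endpoint),
            class = "km_curve")
}

#' @rdname km_estimate
#' @param curve a `km_curve`.
#' @param t time(s) at which to evaluate the step function.
#' @export
survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    past <- curve$times <= tt
    if (!any(past)) 1 else curve$survival[max(which(past))]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier %s curve: n = %d, %d event times\n",
              x$endpoint, x$n, length(x$times)))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected chi-square over the shared event times, with
#' p from the chi-square distribution on k-1 degrees of freedom. With no
#' events anywhere the test is vacuous: chi-square 0, p = 1, with a warning.
#'
#' @param outcomes data frame with `time` and `event`.
#' @param groups group label per row of `outcomes` (>= 2 non-empty groups).
#' @return a `logrank_result` list: `chi_square`, `df`, `p`, `group_sizes`,
#'   `obs`, `exp` (per-group observed and expected event counts).
#' @export
logrank_test <- function(outcomes, groups) {
  outcomes <- as_outcomes(outcomes)
  if (length(groups) != nrow(outcomes))
    stop_giscan("groups must match outcomes row-for-row")
  g <- factor(groups)
  sizes <- table(g)
  if (nlevels(g) < 2)
    stop_giscan("log-rank needs >= 2 non-empty groups")
  if (any(sizes == 0))
    stop_giscan("log-rank group with zero subjects: %s",
                paste(names(sizes)[sizes == 0], collapse = ", "))
  df <- nlevels(g) - 1L
  if (sum(outcomes$event) == 0) {
    warn_giscan("no events in any group; log-rank p = 1")
    res <- list(chi_square = 0, df = df, p = 1,
                group_sizes = as.integer(sizes),
                obs = rep(0, nlevels(g)), exp = rep(0, nlevels(g)))
    names(res$group_sizes) <- levels(g)
    class(res) <- "logrank_result"
    return(res)
  }
  dat <- data.frame(time = outcomes$time, event = outcomes$event, g = g)
  sd_ <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ g, data = dat),
    error = function(e) NULL)
  if (is.null(sd_) || !is.finite(sd_$chisq)) {
    # degenerate risk-set structure (singular variance); fall back to the
    # O-E quadratic form with a generalized inverse
    oev <- logrank_oev(dat$time, dat$event, g)
    d <- oev$obs - oev$exp
    chi <- as.numeric(t(d) %*% MASS::ginv(oev$var) %*% d)
    sd_ <- list(chisq = chi, obs = oev$obs, exp = oev$exp)
  }
  chi <- as.numeric(sd_$chisq)
  res <- list(chi_square = chi, df = df,
              p = stats::pchisq(chi, df, lower.tail = FALSE),
              group_sizes = setNames(as.integer(sizes), levels(g)),
              obs = as.numeric(sd_$obs), exp = as.numeric(sd_$exp))
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.3f on %d df, p = %.4g (n = %s)\n",
              x$chi_square, x$df, x$p,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

# per-group observed/expected event counts and covariance of the log-rank
# statistic, summed over distinct event times (hypergeometric moments)
logrank_oev <- function(time, event, g) {
  g <- as.integer(g)
  k <- max(g)
  obs <- numeric(k); expd <- numeric(k); V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    d <- sum(time == t & event == 1)
    for (i in seq_len(k)) {
      ni <- sum(at & g == i)
      obs[i] <- obs[i] + sum(time == t & event == 1 & g == i)
      expd[i] <- expd[i] + d * ni / n
      for (j in seq_len(k)) {
        nj <- sum(at & g == j)
        if (n > 1)
          V[i, j] <- V[i, j] + d * (ni / n) * ((i == j) - nj / n) * (n - d) / (n - 1)
      }
    }
  }
  list(obs = obs, exp = expd, var = V)
}

#' Univariate survival screen for one panel gene
#'
#' Log-rank comparison of carriers (directional group 1) versus non-carriers
#' (group 0) for a single gene, with the screening eligibility rules applied
#' before interpretation: a gene is ineligible for the DFS screen when it has
#' at most one carrier, and ineligible for the OS screen when no carrier died
#' during follow-up (either way the log-rank is degenerate or dominated by a
#' single subject). Ineligible genes still return their statistics where
#' computable; `eligible` records the flag.
#'
#' @param groups 0/1 carrier label per patient (from [group_by_direction()]).
#' @param outcomes data frame with `time` and `event`, row-matched to
#'   `groups`.
#' @param endpoint `"DFS"` or `"OS"`.
#' @return list: `endpoint`, `n_carriers`, `n_carrier_events`, `chi_square`,
#'   `p`, `eligible`, `reason`.
#' @export
univariate_gene_screen <- function(groups, outcomes, endpoint = c("DFS", "OS")) {
  endpoint <- match.arg(endpoint)
  outcomes <- as_outcomes(outcomes)
  if (length(groups) != nrow(outcomes))
    stop_giscan("groups must match outcomes row-for-row")
  if (!all(groups %in% c(0, 1))) stop_giscan("groups must be 0/1")
  n_car <- sum(groups == 1)
  n_car_ev <- sum(outcomes$event[groups == 1])
  eligible <- TRUE
  reason <- NA_character_
  if (endpoint == "DFS" && n_car <= 1) {
    eligible <- FALSE
    reason <- "carrier arm has <= 1 patient"
  }
  if (endpoint == "OS" && n_car_ev == 0) {
    eligible <- FALSE
    reason <- "no deaths among carriers"
  }
  chi <- NA_real_
  p <- NA_real_
  if (n_car > 0 && n_car < length(groups)) {
    lr <- suppressWarnings(logrank_test(outcomes, groups))
    chi <- lr$chi_square
    p <- lr$p
  } else {
    eligible <- FALSE
    reason <- "single-arm data"
  }
  list(endpoint = endpoint, n_carriers = n_car, n_carrier_events = n_car_ev,
       chi_square = chi, p = p, eligible = eligible, reason = reason)
}

#' Median-CA125 four-subgroup survival analysis
#'
#' Stratifies patients jointly by gene CNV status and preoperative CA125
#' dichotomized at the cohort median: subgroup 1 = CNV and CA125 > median,
#' 2 = CNV and CA125 <= median, 3 = no CNV and CA125 > median, 4 = no CNV and
#' CA125 <= median (the boundary value goes to the low-CA125 arm). Reports
#' the global log-rank across the non-empty subgroups as the headline test
#' plus all pairwise log-rank tests, uncorrected.
#'
#' @param groups 0/1 carrier label per patient for one gene.
#' @param records `clinical_table` row-matched to `groups`.
#' @param endpoint `"DFS"` or `"OS"`.
#' @return list: `subgroups` (per-patient data frame with `label`),
#'   `median_ca125`, `logrank` (global, df = non-empty arms - 1),
#'   `pairwise` (data frame), `endpoint`.
#' @export
ca125_subgroups <- function(groups, records, endpoint = c("DFS", "OS")) {
  endpoint <- match.arg(endpoint)
  if (length(groups) != nrow(records))
    stop_giscan("groups must match records row-for-row")
  time_col <- if (endpoint == "DFS") "dfs_months" else "os_months"
  event_col <- if (endpoint == "DFS") "dfs_event" else "os_event"
  keep <- !is.na(records$ca125) & !is.na(records[[time_col]]) &
    !is.na(records[[event_col]])
  if (any(!keep))
    warn_giscan("excluding %d patient(s) with missing CA125 or %s follow-up",
                sum(!keep), endpoint)
  rec <- records[keep, ]
  grp <- groups[keep]
  med <- median(rec$ca125)
  high <- as.integer(rec$ca125 > med)
  label <- integer(nrow(rec))
  label[grp == 1 & high == 1] <- 1L
  label[grp == 1 & high == 0] <- 2L
  label[grp == 0 & high == 1] <- 3L
  label[grp == 0 & high == 0] <- 4L
  present <- sort(unique(label))
  if (length(present) < 2)
    stop_giscan("fewer than 2 non-empty CA125 subgroups")
  outcomes <- data.frame(time = rec[[time_col]], event = rec[[event_col]])
  global <- logrank_test(outcomes, label)
  pairs <- utils::combn(present, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sel <- label %in% c(a, b)
    lr <- suppressWarnings(logrank_test(outcomes[sel, ], label[sel]))
    data.frame(subgroup_a = a, subgroup_b = b, chi_square = lr$chi_square,
               p = lr$p)
  }))
  list(subgroups = data.frame(patient_id = rec$patient_id, group = grp,
                              ca125 = rec$ca125, ca125_high = high,
                              label = label, stringsAsFactors = FALSE),
       median_ca125 = med, logrank = global, pairwise = pairwise,
       endpoint = endpoint)
}

#' Plot Kaplan-Meier curves by group
#'
#' Minimal base-graphics KM panel used by the pipeline `report`/`survival`
#' stages.
#'
#' @param outcomes data frame with `time` and `event`.
#' @param groups group label per patient.
#' @param main plot title.
#' @return invisibly, the `survfit` object.
#' @export
plot_km <- function(outcomes, groups, main = "") {
  outcomes <- as_outcomes(outcomes)
  dat <- data.frame(time = outcomes$time, event = outcomes$event,
                    g = factor(groups))
  sf <- survival::survfit(survival::Surv(time, event) ~ g, data = dat)
  graphics::plot(sf, col = seq_len(nlevels(dat$g)), lwd = 2,
                 xlab = "months", ylab = "survival", main = main)
  graphics::legend("bottomleft", legend = levels(dat$g), lwd = 2,
                   col = seq_len(nlevels(dat$g)), bty = "n")
  invisible(sf)
}
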