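# Kaplan-Meier, log-rank, gene screens, CA125 subgroups

test_that("classify_recurrence applies the six-month rule inclusively", {
  expect_identical(classify_recurrence(c(4, 12, 6, 6.1)),
                   c("progression", "relapse", "progression", "relapse"))
  expect_error(classify_recurrence(0), "positive")
})

test_that("km_estimate matches the hand-computed product limit", {
  # times {1 event, 2 censored, 3 event}: S(1) = 2/3, S(3) = 0
  out <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimate(out)
  expect_equal(km$times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(survival_at(km, 0), 1)
  expect_equal(survival_at(km, 2.5), 2 / 3)

  all_cens <- km_estimate(data.frame(time = c(5, 8), event = c(0, 0)))
  expect_identical(length(all_cens$times), 0L)
  expect_equal(survival_at(all_cens, c(0, 100)), c(1, 1))

  expect_error(km_estimate(data.frame(time = numeric(), event = integer())),
               ">= 1")
})

test_that("km_estimate equals 1 - ECDF without censoring, and matches the oracle", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    time <- sample(1:6, n, replace = TRUE)  # forces ties
    event <- sample(0:1, n, replace = TRUE, prob = c(0.3, 0.7))
    km <- km_estimate(data.frame(time = time, event = event))
    orc <- oracle_km(time, event)
    expect_equal(km$times, orc$times)
    expect_equal(km$survival, orc$survival)
  }
  time <- c(2, 5, 5, 9, 1)
  km <- km_estimate(data.frame(time = time, event = 1))
  expect_equal(survival_at(km, sort(unique(time))),
               1 - ecdf(time)(sort(unique(time))))
})

test_that("logrank_test matches the brute-force O-E/V oracle", {
  # the worked two-group case: A events at {1,2}, B censored at {3,3}
  out <- data.frame(time = c(1, 2, 3, 3), event = c(1, 1, 0, 0))
  g <- c("A", "A", "B", "B")
  res <- logrank_test(out, g)
  orc <- oracle_logrank2(out$time, out$event, g)
  expect_equal(res$chi_square, orc$chi_square, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  expect_identical(res$df, 1L)

  # identical duplicated groups: perfectly balanced, chi-square 0
  out2 <- data.frame(time = rep(c(2, 4, 6), 2), event = rep(c(1, 0, 1), 2))
  res2 <- logrank_test(out2, rep(c("x", "y"), each = 3))
  expect_equal(res2$chi_square, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)

  expect_error(logrank_test(out, rep("A", 4)), "2 non-empty")
})

test_that("logrank equals the squared standardized O-E on enumerated small datasets", {
  # all event/censor patterns at n = 6, fixed distinct times, balanced groups
  n <- 6
  time <- 1:6
  g <- rep(c(1, 2), each = 3)
  for (mask in 1:(2^n - 1)) {
    event <- as.integer(intToBits(mask)[1:n])
    orc <- oracle_logrank2(time, event, g)
    res <- suppressWarnings(logrank_test(data.frame(time = time, event = event), g))
    expect_equal(res$chi_square, orc$chi_square, tolerance = 1e-8,
                 label = sprintf("pattern %d chi", mask))
    expect_equal(res$p, orc$p, tolerance = 1e-8)
  }
  # tied times with mixed event/censor, unbalanced groups
  set.seed(121)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    time <- sample(1:4, n, replace = TRUE)
    event <- sample(0:1, n, replace = TRUE)
    g <- c(1, 2, sample(1:2, n - 2, replace = TRUE))
    if (sum(event) == 0) next
    orc <- oracle_logrank2(time, event, g)
    res <- suppressWarnings(logrank_test(data.frame(time = time, event = event), g))
    expect_equal(res$chi_square, orc$chi_square, tolerance = 1e-8)
  }
})

test_that("logrank is invariant to group relabeling and time shifts", {
  set.seed(131)
  out <- data.frame(time = rexp(30, 0.1), event = rbinom(30, 1, 0.7))
  g <- sample(c("a", "b"), 30, replace = TRUE)
  r1 <- logrank_test(out, g)
  r2 <- logrank_test(out, ifelse(g == "a", "z2", "z1"))
  out_shift <- transform(out, time = time + 7)
  r3 <- logrank_test(out_shift, g)
  expect_equal(r2$chi_square, r1$chi_square)
  expect_equal(r3$chi_square, r1$chi_square)
})

test_that("logrank power at hazard ratio 4, n = 20 vs 20 (seed 37)", {
  set.seed(37)
  hits <- replicate(200, {
    time <- c(rexp(20, 0.05), rexp(20, 0.2))
    cens <- runif(40, 10, 40)
    out <- data.frame(time = pmin(time, cens),
                      event = as.integer(time <= cens))
    logrank_test(out, rep(1:2, each = 20))$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("no-events input yields the flagged p = 1 result", {
  out <- data.frame(time = c(3, 4, 5, 6), event = 0L)
  expect_warning(res <- logrank_test(out, c(1, 1, 2, 2)), "no events")
  expect_equal(res$p, 1)
})

test_that("screen eligibility mirrors the published exclusion rules", {
  out <- data.frame(time = c(2, 10, 12, 30, 40), event = c(1, 1, 1, 0, 0))

  # one carrier: ineligible for DFS
  s <- suppressWarnings(univariate_gene_screen(c(1, 0, 0, 0, 0), out, "DFS"))
  expect_false(s$eligible)
  expect_match(s$reason, "<= 1 patient")
  expect_identical(s$n_carriers, 1L)

  # carriers without deaths: ineligible for OS
  s2 <- univariate_gene_screen(c(0, 0, 0, 1, 1), out, "OS")
  expect_false(s2$eligible)
  expect_match(s2$reason, "no deaths")
  expect_true(is.finite(s2$p))

  # two carriers with events: eligible, p from the log-rank
  s3 <- univariate_gene_screen(c(1, 1, 0, 0, 0), out, "DFS")
  expect_true(s3$eligible)
  orc <- oracle_logrank2(out$time, out$event, c(1, 1, 0, 0, 0))
  expect_equal(s3$p, orc$p, tolerance = 1e-10)

  # all carriers or no carriers: single-arm, no test
  s4 <- univariate_gene_screen(c(0, 0, 0, 0, 0), out, "DFS")
  expect_false(s4$eligible)
  expect_true(is.na(s4$p))
})

test_that("carrier screens detect a hazard ratio 6 effect in 3/40 carriers (seed 41)", {
  set.seed(41)
  hits <- replicate(200, {
    grp <- c(rep(1L, 3), rep(0L, 37))
    rate <- log(2) / 30 * ifelse(grp == 1, 6, 1)
    t <- rexp(40, rate)
    cens <- runif(40, 36, 72)
    out <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
    univariate_gene_screen(grp, out, "DFS")$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("ca125_subgroups labels the four arms with the boundary in the low arm", {
  clin <- toy_clinical(8, dfs_months = c(5, 8, 12, 20, 25, 30, 35, 40),
                       dfs_event = c(1, 1, 1, 1, 0, 0, 1, 0),
                       ca125 = c(600, 575.5, 100, 900, 50, 700, 575.5, 80))
  # median of these CA125 values
  med <- median(clin$ca125)
  grp <- c(1, 1, 1, 0, 0, 0, 0, 0)
  res <- ca125_subgroups(grp, clin, "DFS")
  expect_equal(res$median_ca125, med)
  lab <- res$subgroups$label
  expect_identical(lab[1], 1L)               # CNV, CA125 > median
  expect_identical(lab[2], 2L)               # CNV, CA125 == median -> low arm
  expect_identical(lab[5], 4L)               # no CNV, low CA125
  # labels partition the cohort
  expect_identical(sum(table(lab)), 8L)
  expect_identical(res$logrank$df, length(unique(lab)) - 1L)
  expect_true(all(res$pairwise$p >= 0 & res$pairwise$p <= 1))
})

test_that("ca125_subgroups excludes missing CA125 with a warning", {
  clin <- toy_clinical(5, dfs_months = c(5, 8, 12, 20, 25),
                       dfs_event = c(1, 1, 1, 0, 0),
                       ca125 = c(600, NA, 100, 900, 50))
  expect_warning(res <- ca125_subgroups(c(1, 1, 0, 0, 0), clin, "DFS"),
                 "excluding 1")
  expect_identical(nrow(res$subgroups), 4L)
})
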