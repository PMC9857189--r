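# reference model, Z-scores, CNV calls, Gi score

test_that("build_reference computes mu/sigma with flooring", {
  # two controls {1, 3}: mu = 2, sample SD = sqrt(2)
  ref <- toy_reference(cbind(c(1, 5), c(3, 5)))
  expect_equal(ref$mu[1], 2)
  expect_equal(ref$sigma[1], sqrt(2))
  # identical controls: sigma floored at 0.05 * mu
  expect_equal(ref$sigma[2], 0.05 * 5)

  expect_error(build_reference(list(toy_profile(1:3))), "at least 2")
  p1 <- toy_profile(1:3, sample_id = "a"); p1$norm_depth <- p1$raw_depth
  p2 <- toy_profile(1:4, sample_id = "b"); p2$norm_depth <- p2$raw_depth
  expect_error(build_reference(list(p1, p2)), "mismatched")
})

test_that("reference estimates concentrate at n = 20 (seed 11)", {
  set.seed(11)
  n_feat <- 1000
  depth_mat <- matrix(rnorm(n_feat * 20, 10, 1), n_feat, 20)
  ref <- toy_reference(depth_mat)
  # sampling distribution: mean within 10 +/- 0.7, SD within [0.6, 1.4]
  expect_gte(mean(abs(ref$mu - 10) < 0.7), 0.95)
  expect_gte(mean(ref$sigma > 0.6 & ref$sigma < 1.4), 0.95)
})

test_that("zscore matches its closed form and flags propagate", {
  ref <- toy_reference(cbind(c(10, 10), c(10, 10)))
  ref$mu <- c(10, 10); ref$sigma <- c(2, 2)
  prof <- toy_profile(c(10, 14)); prof$norm_depth <- prof$raw_depth
  z <- zscore(prof, ref)
  expect_equal(z$z, c(0, 2))

  prof$flag[2] <- "gc_out_of_range"
  expect_true(is.na(zscore(prof, ref)$z[2]))

  bad <- toy_profile(c(10, 14, 3)); bad$norm_depth <- bad$raw_depth
  expect_error(zscore(bad, ref), "mismatched")
})

test_that("a control scored against its own cohort reference centers at 0 (seed 13)", {
  set.seed(13)
  depth_mat <- matrix(rnorm(1000 * 20, 10, 1), 1000, 20)
  ref <- toy_reference(depth_mat)
  prof <- toy_profile(depth_mat[, 1]); prof$norm_depth <- prof$raw_depth
  z <- zscore(prof, ref)
  expect_lt(abs(mean(z$z)), 0.2)
})

test_that("Z-scores are invariant to a common positive depth rescaling", {
  set.seed(21)
  depth_mat <- matrix(rnorm(200 * 5, 10, 1), 200, 5)
  prof <- toy_profile(depth_mat[, 1] * 1.7); prof$norm_depth <- prof$raw_depth
  z1 <- zscore({p <- toy_profile(depth_mat[, 1]); p$norm_depth <- p$raw_depth; p},
               toy_reference(depth_mat))
  z2 <- zscore(prof, toy_reference(depth_mat * 1.7))
  expect_equal(z2$z, z1$z, tolerance = 1e-10)
})

test_that("call_cnv applies strict +/-2 thresholds", {
  expect_identical(call_cnv(c(2.5, -2.5, 2, -2, 0, NA)),
                   c("AMP", "DEL", "NEUTRAL", "NEUTRAL", "NEUTRAL", NA))
})

test_that("group_by_direction follows the panel direction only", {
  expect_identical(group_by_direction(c(3, -3, -5, 2, NA), "AMP"),
                   c(1L, 0L, 0L, 0L, 0L))
  expect_identical(group_by_direction(c(-3, 3, -2, NA), "DEL"),
                   c(1L, 0L, 0L, 0L))
  # agreement with call_cnv: group 1 implies the matching call
  set.seed(3)
  z <- rnorm(500, 0, 2)
  dirs <- sample(c("AMP", "DEL"), 500, replace = TRUE)
  grp <- group_by_direction(z, dirs)
  calls <- call_cnv(z)
  expect_true(all(calls[grp == 1] == dirs[grp == 1]))
})

test_that("gi_score matches direct summation and is additive", {
  expect_equal(gi_score(toy_zprofile(c(0, 0, 0)))$gi, 0)
  expect_equal(gi_score(toy_zprofile(c(2, -3, 0.5)))$gi, 5.5)

  set.seed(17)
  z1 <- rnorm(40); z2 <- rnorm(25)
  g1 <- gi_score(toy_zprofile(z1))$gi
  g2 <- gi_score(toy_zprofile(z2))$gi
  g12 <- gi_score(toy_zprofile(c(z1, z2)))$gi
  expect_equal(g12, g1 + g2)
  expect_equal(g12, oracle_gi(c(z1, z2)))

  # missing features are skipped; all-missing errors
  zp <- toy_zprofile(c(1, NA, -2))
  expect_equal(gi_score(zp)$gi, 3)
  expect_identical(gi_score(zp)$n_features, 2L)
  expect_error(gi_score(toy_zprofile(c(NA, NA))), "no non-missing")

  # sex-chromosome bins excluded by default, included on request
  zx <- toy_zprofile(c(2, 5), chrom = c("chr1", "chrX"))
  expect_equal(gi_score(zx)$gi, 2)
  expect_equal(gi_score(zx, include_sex_chroms = TRUE)$gi, 7)
})

test_that("cancer-like z shift lifts Gi above the control 95th percentile (seed 19)", {
  set.seed(19)
  gi_ctrl <- replicate(20, gi_score(toy_zprofile(rnorm(1000)))$gi)
  gi_case <- gi_score(toy_zprofile(c(rnorm(900), rnorm(100, 4, 1))))$gi
  expect_gt(gi_case, quantile(gi_ctrl, 0.95))
})

test_that("compare_gi reproduces the exact rank-sum null", {
  res <- compare_gi(c(1, 2), c(3, 4))
  expect_equal(res$p, 1 / 3)
  expect_equal(res$p, oracle_ranksum_p(c(1, 2), c(3, 4)))
  expect_identical(res$method, "exact")

  # randomised small instances against exhaustive enumeration
  set.seed(47)
  for (i in 1:20) {
    a <- round(rnorm(sample(2:5, 1)), 3)
    b <- round(rnorm(sample(2:5, 1), 0.5), 3)
    expect_equal(compare_gi(a, b)$p, oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
  }

  x <- c(5, 6, 7)
  expect_equal(suppressWarnings(compare_gi(x, x))$p, 1)
  expect_warning(compare_gi(c(1, 1), c(1, 1)), "tied")
})

test_that("rank-sum power at a 2 SD shift, n = 20 vs 20 (seed 23)", {
  set.seed(23)
  hits <- replicate(200, {
    a <- rnorm(20); b <- rnorm(20, 2)
    compare_gi(a, b)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("ten-feature profiles match a hand-rolled full computation", {
  set.seed(61)
  panel <- load_gene_panel(default_panel_path())[1:10, ]
  for (rep in 1:10) {
    mu <- runif(10, 5, 15)
    sigma <- runif(10, 0.5, 2)
    depth_mat <- sapply(1:4, function(j) rnorm(10, mu, sigma))
    ref <- toy_reference(depth_mat, feature_type = "gene", ids = panel$gene)
    x <- pmax(0.01, rnorm(10, mu, 3 * sigma))
    prof <- toy_profile(x, feature_type = "gene")
    prof$feature_id <- panel$gene
    prof$norm_depth <- prof$raw_depth
    z <- zscore(prof, ref)
    z_hand <- (x - rowMeans(depth_mat)) /
      pmax(apply(depth_mat, 1, sd), pmax(1e-6, 0.05 * rowMeans(depth_mat)))
    expect_equal(z$z, z_hand, tolerance = 1e-12)
    expect_equal(gi_score(z, features = "gene")$gi, sum(abs(z_hand)))
    calls <- cnv_call_table(z, panel)
    hand_call <- ifelse(z_hand > 2, "AMP", ifelse(z_hand < -2, "DEL", "NEUTRAL"))
    hand_grp <- as.integer(ifelse(panel$direction == "AMP", z_hand > 2, z_hand < -2))
    expect_identical(calls$call, hand_call)
    expect_identical(calls$group, hand_grp)
  }
})

test_that("planted +k sigma effects are grouped 1 for k >= 4 (seed 31)", {
  set.seed(31)
  hits <- replicate(200, {
    ref <- toy_reference(matrix(rnorm(100 * 20, 10, 1), 100, 20))
    x <- rnorm(100, 10, 1)
    x[1] <- 10 + 4  # +4 sigma on the first feature
    prof <- toy_profile(x); prof$norm_depth <- prof$raw_depth
    z <- zscore(prof, ref)
    group_by_direction(z$z[1], "AMP") == 1L
  })
  expect_gte(mean(hits), 0.95)
})

test_that("downsample thinning behaves and full fraction is the identity", {
  set.seed(71)
  n <- 600
  gc <- toy_gc(n)
  depth <- rpois(n, 5000) / 1000  # ~5x over 100 kb bins at 100 bp reads
  genes <- as.data.frame(toy_profile(rnorm(33, 5, 0.5), gc = toy_gc(33),
                                     feature_type = "gene"))[1:7]
  prof <- depth_profile(rbind(as.data.frame(toy_profile(depth, gc = gc))[1:7],
                              genes), "s")
  profs <- lapply(1:10, function(j) {
    feats <- as.data.frame(prof)[1:7]
    feats$raw_depth <- pmax(0, feats$raw_depth + rnorm(nrow(feats), 0, 0.2))
    loess_gc_normalize(depth_profile(feats, paste0("c", j)))
  })
  ref <- build_reference(profs)

  expect_error(downsample_concordance(prof, 0, ref, 1), "target_fraction")
  expect_equal(downsample_concordance(prof, 1, ref, 1)$r, 1)

  # binomial thinning preserves expected depth to within 2% of the fraction
  ds <- downsample_concordance(prof, 0.2, ref, seed = 5)
  thin_raw_mean <- mean(ds$thinned_profile$raw_depth) * 0.2  # undo the rescale
  expect_lt(abs(thin_raw_mean / mean(prof$raw_depth) - 0.2), 0.02 * 0.2)
})
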