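test_that("residual maps are signed reconstruction-minus-input differences", {
  v <- make_volume_fixture(c(6, 6, 4), fill = "ramp")
  r0 <- residual_map(v, v)
  expect_true(all(r0$signed == 0) && all(r0$magnitude == 0))
  r1 <- residual_map(v, v + 0.1)
  expect_equal(r1$signed, array(0.1, dim(v)))
  expect_equal(r1$magnitude, array(0.1, dim(v)))
  rn <- residual_map(v, v - 0.2)
  expect_equal(rn$signed, array(-0.2, dim(v)))
  expect_equal(rn$magnitude, array(0.2, dim(v)))
  expect_error(residual_map(v, array(0, c(3, 3, 3))), "shape")
})

test_that("effective-atrophy thresholding is strictly greater-than", {
  v <- array(0, c(2, 2, 2))
  m <- array(0, c(2, 2, 2))
  m[1] <- 0.030; m[2] <- 0.031; m[3] <- -0.05
  rm <- residual_map(v, m)   # signed = m
  am <- effective_atrophy_mask(rm, threshold = 0.03)
  expect_false(am$mask[1])                  # exactly at threshold: not flagged
  expect_true(am$mask[2])
  expect_true(am$mask[3])                   # magnitude channel by default
  ams <- effective_atrophy_mask(rm, threshold = 0.03, use_signed = TRUE)
  expect_false(ams$mask[3])                 # signed channel ignores negatives
  empty <- effective_atrophy_mask(residual_map(v, v), threshold = 0.03)
  expect_false(any(empty$mask))
  expect_error(effective_atrophy_mask(rm, threshold = 0), "> 0")
})

test_that("flagged-voxel counts match a brute-force scan on random maps", {
  set.seed(5)
  for (rep in 1:10) {
    vals <- array(rnorm(4 * 5 * 3, sd = 0.05), c(4, 5, 3))
    rm <- residual_map(array(0, dim(vals)), vals)
    thr <- runif(1, 0.01, 0.08)
    am <- effective_atrophy_mask(rm, threshold = thr)
    brute <- sum(vapply(seq_along(vals), function(i) abs(vals[i]) > thr,
                        logical(1)))
    expect_identical(sum(am$mask), brute)
  }
})

test_that("frequency masks use the strict exceeding rule", {
  d <- c(2, 2, 1)
  mk <- function(on) { a <- array(FALSE, d); a[on] <- TRUE; a }
  masks <- list(mk(1:2), mk(1:2), mk(1), mk(1), mk(c(1, 3)))
  fm <- group_frequency_mask(masks, freq_threshold = 0.60)
  expect_equal(fm$frequency[1], 1.0)
  expect_equal(fm$frequency[2], 0.4)
  expect_equal(fm$frequency[3], 0.2)
  expect_true(fm$binary[1])
  # flagged in 3 of 5 -> 0.6, not > 0.6 -> excluded
  masks2 <- list(mk(1), mk(1), mk(1), mk(2), mk(2))
  fm2 <- group_frequency_mask(masks2, freq_threshold = 0.60)
  expect_equal(fm2$frequency[1], 0.6)
  expect_false(fm2$binary[1])
  # flagged in 4 of 5 -> 0.8 > 0.6 -> kept
  fm3 <- group_frequency_mask(list(mk(1), mk(1), mk(1), mk(1), mk(2)))
  expect_true(fm3$binary[1])
  expect_error(group_frequency_mask(list()), "at least one")
  expect_error(group_frequency_mask(list(mk(1), array(TRUE, c(3, 3, 3)))),
               "common shape")
})

test_that("frequencies match per-voxel counting on random mask sets", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    masks <- lapply(seq_len(n), function(i) array(runif(24) < 0.4, c(4, 3, 2)))
    fm <- group_frequency_mask(masks)
    for (v in sample(24, 6)) {
      cnt <- sum(vapply(masks, function(m) m[v], logical(1)))
      expect_equal(fm$frequency[v], cnt / n)
      expect_identical(fm$binary[v], cnt / n > 0.6)
    }
    expect_true(all(abs(fm$frequency * n - round(fm$frequency * n)) < 1e-12))
  }
})

test_that("cluster filtering keeps components of at least min_size intact", {
  m <- array(FALSE, c(20, 20, 3))
  m[1:7, 1:7, 1] <- TRUE               # 49-voxel plate
  f49 <- cluster_filter(m, min_size = 50)
  expect_false(any(f49))
  m[1:7, 1:7, 2] <- TRUE               # grow to 98 connected voxels
  f98 <- cluster_filter(m, min_size = 50)
  expect_identical(f98, array(m > 0, dim(m)))
  m50 <- array(FALSE, c(10, 10, 1)); m50[1:10, 1:5, 1] <- TRUE
  expect_true(all(cluster_filter(m50, min_size = 50)[m50]))
  expect_false(any(cluster_filter(array(FALSE, c(5, 5, 5)), min_size = 2)))
  expect_error(cluster_filter(m, min_size = 0), "min_size")
})

test_that("surviving components match a flood-fill oracle on random masks", {
  set.seed(7)
  for (rep in 1:12) {
    mask <- array(runif(6 * 6 * 4) < 0.35, c(6, 6, 4))
    min_size <- sample(2:6, 1)
    got <- cluster_filter(mask, min_size = min_size)
    oc <- oracle_components(mask, 26L)
    keep <- which(oc$sizes >= min_size)
    expected <- array(oc$labels %in% keep, dim(mask))
    expect_identical(got, expected)
  }
  # 6-connectivity variant agrees with its oracle too
  for (rep in 1:5) {
    mask <- array(runif(5 * 5 * 3) < 0.4, c(5, 5, 3))
    got <- cluster_filter(mask, min_size = 3, connectivity = 6)
    oc <- oracle_components(mask, 6L)
    expected <- array(oc$labels %in% which(oc$sizes >= 3), dim(mask))
    expect_identical(got, expected)
  }
})

test_that("cluster filtering is idempotent", {
  set.seed(8)
  for (rep in 1:5) {
    mask <- array(runif(8 * 8 * 3) < 0.3, c(8, 8, 3))
    once <- cluster_filter(mask, min_size = 4)
    twice <- cluster_filter(once, min_size = 4)
    expect_identical(twice, once)
  }
})

test_that("raising thresholds never enlarges masks", {
  set.seed(9)
  vals <- array(abs(rnorm(10 * 10 * 4, sd = 0.05)), c(10, 10, 4))
  rm <- residual_map(array(0, dim(vals)), vals)
  thrs <- c(0.01, 0.03, 0.05, 0.08)
  masks <- lapply(thrs, function(t) effective_atrophy_mask(rm, t)$mask)
  for (i in seq_len(length(thrs) - 1))
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  subj <- lapply(1:6, function(i)
    array(runif(10 * 10 * 4) < 0.5, c(10, 10, 4)))
  for (ft in c(0.2, 0.4, 0.6)) {
    lo <- group_frequency_mask(subj, ft)$binary
    hi <- group_frequency_mask(subj, ft + 0.2)$binary
    expect_true(all(hi <= lo))
  }
})

test_that("the voxelwise t-test matches stats::t.test and its edge cases", {
  set.seed(10)
  d <- c(5, 4, 3)
  ga <- lapply(1:6, function(i) array(rnorm(prod(d)), d))
  gb <- lapply(1:5, function(i) array(rnorm(prod(d), mean = 0.3), d))
  res <- voxelwise_ttest_mask(ga, gb, min_size = 1)
  for (v in sample(prod(d), 8)) {
    a <- vapply(ga, function(x) x[v], numeric(1))
    b <- vapply(gb, function(x) x[v], numeric(1))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[v], tt$p.value, tolerance = 1e-10)
  }
  # identical groups: t = 0 everywhere, empty mask
  same <- voxelwise_ttest_mask(ga, ga, min_size = 1)
  expect_true(all(same$t == 0))
  expect_false(any(same$mask))
  # enormous effect at one voxel is flagged before cluster filtering
  ga2 <- lapply(1:10, function(i) { x <- array(rnorm(prod(d)), d); x[1] <- rnorm(1); x })
  gb2 <- lapply(1:10, function(i) { x <- array(rnorm(prod(d)), d); x[1] <- rnorm(1, 10); x })
  big <- voxelwise_ttest_mask(ga2, gb2, min_size = 1)
  expect_true(big$p[1] < 0.05)
  # zero-variance voxels are never significant
  gc <- lapply(1:4, function(i) { x <- array(rnorm(prod(d)), d); x[2] <- 1; x })
  gd <- lapply(1:4, function(i) { x <- array(rnorm(prod(d)), d); x[2] <- 1; x })
  z <- voxelwise_ttest_mask(gc, gd, min_size = 1)
  expect_equal(z$p[2], 1)
  expect_error(voxelwise_ttest_mask(ga[1], gb), "at least 2")
})

test_that("subject residual scores are masked means (or suprathreshold sums)", {
  v <- array(0, c(4, 4, 2))
  mask <- array(TRUE, c(4, 4, 2))
  expect_equal(subject_residual_score(residual_map(v, v), mask), 0)
  r <- residual_map(v, v + 0.05)
  expect_equal(subject_residual_score(r, mask), 0.05)
  set.seed(11)
  vals <- array(rnorm(32, sd = 0.05), c(4, 4, 2))
  rm <- residual_map(v, vals)
  mask2 <- array(runif(32) < 0.6, c(4, 4, 2))
  expect_equal(subject_residual_score(rm, mask2), mean(abs(vals)[mask2]))
  expect_equal(subject_residual_score(rm, mask2, method = "suprathreshold_sum",
                                      threshold = 0.03),
               sum(abs(vals)[mask2][abs(vals)[mask2] > 0.03]))
  expect_error(subject_residual_score(rm, mask2 & FALSE), "empty")
})

test_that("z-score standardization has sample mean 0 and sd 1", {
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize_scores(rep(2, 5)), "spread")
  expect_error(standardize_scores(1), "at least 2")
  set.seed(12)
  s <- rnorm(40, 5, 2)
  z <- standardize_scores(s)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  # against explicit reference statistics
  z2 <- standardize_scores(s, center = 5, scale = 2)
  expect_equal(z2, (s - 5) / 2)
})

test_that("ROC AUC equals the all-pairs probability with ties at one half", {
  expect_equal(roc_auc(c(0, 1), c(FALSE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(1, 0), c(FALSE, TRUE))$auc, 0)
  expect_equal(roc_auc(rep(0.7, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))$auc,
               0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both classes")
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(8:20, 1)
    sc <- sample(round(rnorm(n), 1))     # coarse values force ties
    lb <- runif(n) < 0.5
    if (!any(lb) || all(lb)) next
    r <- roc_auc(sc, lb)
    expect_equal(r$auc, oracle_auc(sc, lb), tolerance = 1e-12)
    # curve endpoints span (0,0) to (1,1)
    expect_equal(unlist(r$curve[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
    expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")],
                        use.names = FALSE), c(1, 1))
  }
})

test_that("AUC agrees with pROC on a random problem", {
  skip_if_not_installed("pROC")
  set.seed(14)
  sc <- rnorm(30)
  lb <- runif(30) < 0.4
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("dice overlap behaves on nested, disjoint and empty masks", {
  a <- array(FALSE, c(4, 4, 2)); a[1:8] <- TRUE
  b <- a
  expect_equal(dice(a, b), 1)
  d <- array(FALSE, c(4, 4, 2)); d[9:16] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_equal(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
  half <- array(FALSE, c(4, 4, 2)); half[1:4] <- TRUE
  expect_equal(dice(a, half), 2 * 4 / (8 + 4))
})

test_that("threshold calibration tracks the reference quantile", {
  set.seed(15)
  maps <- lapply(1:4, function(i)
    residual_map(array(0, c(6, 6, 3)), array(rnorm(108, sd = 0.02), c(6, 6, 3))))
  region <- array(TRUE, c(6, 6, 3))
  thr <- calibrate_threshold(maps, region, q = 0.95)
  vals <- unlist(lapply(maps, function(m) m$magnitude))
  expect_equal(thr, unname(quantile(vals, 0.95)))
  expect_lt(mean(vals > thr), 0.06)
})

test_that("binary erosion removes exactly the voxels with outside neighbours", {
  set.seed(16)
  for (rep in 1:6) {
    m <- array(runif(7 * 6 * 5) < 0.7, c(7, 6, 5))
    er <- erode_mask(m, 1)
    d <- dim(m)
    for (v in sample(prod(d), 20)) {
      p <- arrayInd(v, d)
      nb <- rbind(p + c(1, 0, 0), p - c(1, 0, 0), p + c(0, 1, 0),
                  p - c(0, 1, 0), p + c(0, 0, 1), p - c(0, 0, 1))
      inside <- apply(nb, 1, function(q)
        all(q >= 1) && all(q <= d) && m[q[1], q[2], q[3]])
      expect_identical(er[v], m[v] && all(inside))
    }
  }
  # iterated erosion nests
  m <- array(TRUE, c(8, 8, 8))
  e1 <- erode_mask(m, 1); e2 <- erode_mask(m, 2)
  expect_true(all(e2 <= e1) && all(e1 <= m))
  expect_identical(sum(e1), 216L)
  # 2D matrices erode with the 4-neighbourhood
  s <- matrix(TRUE, 5, 5)
  expect_identical(sum(erode_mask(s, 1)), 9L)
})
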