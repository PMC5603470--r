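test_that("mask_volume is count times voxel volume", {
  img <- suv_image(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
  m <- seg_mask(array(TRUE, c(10, 10, 10)), img)
  expect_equal(mask_volume(m), 8.0)
  expect_warning(v0 <- mask_volume(seg_mask(array(FALSE, c(10, 10, 10)),
                                            img)), "empty")
  expect_equal(v0, 0)
  set.seed(2)
  r <- array(runif(1000) < 0.3, c(10, 10, 10))
  vol <- mask_volume(seg_mask(r, img))
  n <- 0; for (i in seq_along(r)) if (r[i]) n <- n + 1   # counting oracle
  expect_equal(vol, n * 0.008)
})

test_that("ratio_stats basics and oracle", {
  g <- c(10, 20, 40, 80)
  expect_equal(ratio_stats(g, g)$ratio_mean, 1)
  expect_equal(ratio_stats(g, g)$ratio_sd, 0)
  expect_equal(ratio_stats(2 * g, g)$ratio_mean, 2)
  set.seed(4)
  m <- runif(20, 5, 500); gg <- runif(20, 5, 500)
  rs <- ratio_stats(m, gg)
  rr <- numeric(20); for (j in 1:20) rr[j] <- m[j] / gg[j]
  expect_equal(rs$ratio_mean, mean(rr))
  expect_equal(rs$ratio_sd, sqrt(sum((rr - mean(rr))^2) / 19))
  expect_error(ratio_stats(m, c(gg[-1], 0)), "zero")
  expect_error(ratio_stats(1, 1), "at least 2")
})

test_that("spearman: exact values, ties, and reference agreement", {
  x <- c(1, 3, 9, 12, 20, 21, 30, 31, 40, 55)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    xx <- sample(1:8, n, replace = TRUE)       # heavy ties
    yy <- xx + sample(0:3, n, replace = TRUE)
    if (length(unique(yy)) < 2) next
    sp <- spearman_cor(xx, yy)
    ct <- suppressWarnings(cor.test(xx, yy, method = "spearman",
                                    exact = FALSE))
    expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sp$p_value, ct$p.value, tolerance = 1e-12)
  }
  # exact permutation p equals cor.test's exact distribution (n < 10)
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    xx <- rnorm(n); yy <- rnorm(n)
    sp <- spearman_cor(xx, yy)
    expect_identical(sp$method, "exact-permutation")
    ct <- cor.test(xx, yy, method = "spearman", exact = TRUE)
    expect_equal(sp$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("spearman invariant under strictly monotone transforms", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    x <- runif(n); y <- runif(n)
    base <- spearman_cor(x, y)
    tr <- spearman_cor(exp(3 * x), y^3 + 2 * y)
    expect_equal(tr$rho, base$rho, tolerance = 1e-12)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("ICC(A,1): identity, shift sensitivity, and MS oracle", {
  x <- c(10, 25, 31, 47, 60, 72, 90, 105)
  expect_equal(icc_agreement(x, x)$icc, 1)
  # absolute agreement is penalized by a constant shift, consistency is not
  y <- x + 50
  ic <- icc_agreement(x, y)
  k <- 2; n <- length(x)
  dat <- cbind(x, y); grand <- mean(dat)
  msr <- k * sum((rowMeans(dat) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(dat) - grand)^2) / (k - 1)
  mse <- sum((dat - outer(rowMeans(dat), colMeans(dat), "+") + grand)^2) /
    ((n - 1) * (k - 1))
  icc_consistency <- (msr - mse) / (msr + (k - 1) * mse)
  expect_lt(ic$icc, icc_consistency)
  expect_error(icc_agreement(rep(2, 6), rep(2, 6)), "zero total variance")
  expect_error(icc_agreement(1:3, 3:1), "at least 4")
})

test_that("ICC matches the aov mean-square oracle on random fixtures", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(6:40, 1)
    x <- runif(n, 10, 500); y <- x * runif(1, 0.6, 1.4) + rnorm(n, 0, 40)
    ic <- icc_agreement(x, y)
    df <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(v ~ subj + rater, data = df))[[1]][, "Mean Sq"]
    expect_equal(ic$msr, ms[1], tolerance = 1e-9)
    expect_equal(ic$msc, ms[2], tolerance = 1e-9)
    expect_equal(ic$mse, ms[3], tolerance = 1e-9)
    k <- 2
    icc_ref <- (ms[1] - ms[3]) /
      (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
    expect_equal(ic$icc, icc_ref, tolerance = 1e-12)
    expect_lte(ic$ci95[1], ic$icc)
    expect_gte(ic$ci95[2], ic$icc)
  }
})

test_that("bland_altman: exact cases, antisymmetry, loa identity", {
  g <- c(100, 220, 310, 470)
  ba0 <- bland_altman(g, g)
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd, 0)
  ba5 <- bland_altman(g + 5, g)
  expect_equal(ba5$bias, 5); expect_equal(ba5$sd, 0)
  set.seed(15)
  for (rep in 1:10) {
    m <- runif(15, 10, 900); gg <- runif(15, 10, 900)
    ba <- bland_altman(m, gg)
    d <- m - gg
    expect_equal(ba$bias, sum(d) / 15)
    expect_equal(ba$sd, sd(d))
    expect_equal(ba$loa95, ba$bias + c(-1.96, 1.96) * ba$sd,
                 tolerance = 1e-12)
    rev <- bland_altman(gg, m)
    expect_equal(rev$bias, -ba$bias)
    expect_equal(rev$sd, ba$sd)
  }
})

test_that("agreement_report assembles one row per method", {
  set.seed(16)
  gtv <- runif(12, 50, 800)
  mtv <- list("mo-pet" = gtv * rnorm(12, 1.1, 0.1),
              "suv-2.0" = gtv * rnorm(12, 1.0, 0.3))
  rep_ <- agreement_report(mtv, gtv)
  expect_equal(nrow(rep_), 2L)
  expect_identical(rep_$method, c("mo-pet", "suv-2.0"))
  expect_true(all(rep_$icc_lo <= rep_$icc & rep_$icc <= rep_$icc_hi))
  expect_true(all(abs(rep_$spearman_rho) <= 1))
  p <- tempfile(fileext = ".csv")
  write_agreement(rep_, p)
  back <- read.csv(p)
  expect_equal(back$ratio_mean, rep_$ratio_mean, tolerance = 1e-12)
})
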