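test_that("build_histogram rejects degenerate and invalid input", {
  expect_error(build_histogram(numeric(0), 16), "empty input")
  expect_error(build_histogram(rep(3.0, 100), 16), "degenerate")
  expect_error(build_histogram(c(1, NA, 2), 16), "finite")
  expect_error(build_histogram(c(1, -0.5, 2), 16), ">= 0")
  expect_error(build_histogram(c(1, 2), 1), "n_bins")
})

test_that("uniform occupancy and bin conventions", {
  h <- build_histogram(c(0, 1, 2, 3), n_bins = 4)
  expect_equal(h$p, rep(0.25, 4))
  expect_equal(h$bin_edges, seq(0, 3, length.out = 5))
  # maximum value lands in the last bin (right edge inclusive there)
  expect_equal(sum(h$counts), 4L)
  expect_equal(h$value_min, 0)
  expect_equal(h$value_max, 3)
})

test_that("histogram matches brute-force per-bin counting", {
  set.seed(11)
  for (rep in 1:3) {
    v <- c(runif(2000, 0, 20), rexp(1000, 1 / 3))
    nb <- sample(c(16, 37, 64), 1)
    h <- build_histogram(v, nb)
    expect_equal(h$counts, oracle_hist_counts(v, h$bin_edges))
    expect_equal(sum(h$p), 1, tolerance = 1e-12)
    expect_true(all(h$p >= 0))
  }
})

test_that("class_statistics: whole-histogram and delta cases", {
  set.seed(3)
  v <- runif(500, 0, 10)
  h <- build_histogram(v, 32)
  cs <- class_statistics(h)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$p, 1)
  expect_equal(cs$mu, sum(h$mids * h$p))
  # two delta masses: point-mass class has variance exactly 0; a class
  # straddling only empty bins is flagged empty with zero moments
  hd <- build_histogram(c(rep(1, 50), rep(9, 1)), 16)
  cs2 <- class_statistics(hd, thresholds = c(3, 5))
  expect_identical(cs2$empty, c(FALSE, TRUE, FALSE))
  expect_identical(cs2$var[1], 0)
  expect_identical(cs2$p[2], 0)
  hd2 <- build_histogram(c(rep(1, 50), rep(1.9, 1)), 4)
  cs3 <- class_statistics(hd2, thresholds = 1.5)
  expect_identical(cs3$var[1], 0)
})

test_that("class_statistics matches naive weighted-moments oracle", {
  set.seed(21)
  for (rep in 1:5) {
    h <- random_histogram(48, 1500)
    nt <- sample(1:3, 1)
    th <- sort(runif(nt, h$value_min + 1e-6, h$value_max - 1e-6))
    if (any(diff(th) <= 0)) next
    cs <- class_statistics(h, th)
    expect_equal(sum(cs$p), 1, tolerance = 1e-9)
    cuts <- mopet:::threshold_to_cut(h, th)
    bounds <- c(0, cuts, length(h$p))
    for (k in seq_len(nrow(cs))) {
      if (bounds[k + 1] == bounds[k]) next
      m <- oracle_class_moments(h$mids, h$p, bounds[k] + 1, bounds[k + 1])
      expect_equal(cs$p[k], unname(m["p"]), tolerance = 1e-12)
      if (m["p"] > 0) {
        expect_equal(cs$mu[k], unname(m["mu"]), tolerance = 1e-9)
        expect_equal(cs$var[k], unname(m["var"]), tolerance = 1e-9)
        # mean inside the class bounds
        expect_gte(cs$mu[k], h$bin_edges[bounds[k] + 1])
        expect_lte(cs$mu[k], h$bin_edges[bounds[k + 1] + 1])
      }
    }
  }
})

test_that("class_statistics range and ordering errors", {
  h <- build_histogram(runif(100, 0, 5), 16)
  expect_error(class_statistics(h, 7), "outside")
  expect_error(class_statistics(h, -1), "outside")
  expect_error(class_statistics(h, c(3, 2)), "increasing")
  # a threshold inside a bin assigns that bin to the lower class
  h2 <- build_histogram(c(0, 1, 2, 3), 4)   # bins [0,.75) [.75,1.5) ...
  cs <- class_statistics(h2, thresholds = 1.0)  # inside bin 2
  expect_equal(cs$p[1], 0.5)  # bins 1 and 2 (values 0 and 1) below
})
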