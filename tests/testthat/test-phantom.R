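test_that("empty phantom is a constant background volume", {
  spec <- phantom_spec(shape = c(16, 16, 16), spacing = c(2, 2, 2),
                       background_suv = 1.3,
                       spheres = data.frame()[0, ],
                       psf_fwhm = 0, noise_coef = 0, seed = 1)
  ph <- generate_phantom(spec)
  expect_true(all(ph$image$data == 1.3))
  expect_length(ph$truth, 0)
})

test_that("ground-truth mask volume approaches the analytic sphere", {
  ph <- generate_phantom(phantom_spec(
    shape = c(40, 40, 40), spacing = c(1, 1, 1), background_suv = 1,
    spheres = data.frame(x = 19.5, y = 19.5, z = 19.5, diameter = 20,
                         lbr = 4),
    psf_fwhm = 0, noise_coef = 0, seed = 1))
  vol_mm3 <- sum(ph$truth[[1]]$mask) * 1
  expect_equal(vol_mm3, 4 / 3 * pi * 10^3, tolerance = 0.02)
})

test_that("phantoms are seed-deterministic; truth ignores degradation", {
  s1 <- sphere_phantom(diameter = 17, lbr = 4, psf_fwhm = 6,
                       noise_coef = 0.1, seed = 7)
  s2 <- sphere_phantom(diameter = 17, lbr = 4, psf_fwhm = 6,
                       noise_coef = 0.1, seed = 7)
  s3 <- sphere_phantom(diameter = 17, lbr = 4, psf_fwhm = 6,
                       noise_coef = 0.1, seed = 8)
  expect_identical(s1$image$data, s2$image$data)
  expect_false(identical(s1$image$data, s3$image$data))
  clean <- sphere_phantom(diameter = 17, lbr = 4)
  expect_identical(s1$truth[[1]]$mask, clean$truth[[1]]$mask)
})

test_that("overlapping spheres and bad parameters are rejected", {
  expect_error(phantom_spec(spheres = data.frame(
    x = c(30, 40), y = c(30, 30), z = c(30, 30),
    diameter = c(20, 20), lbr = c(4, 4))), "overlap")
  expect_error(phantom_spec(spheres = data.frame(
    x = 30, y = 30, z = 30, diameter = 20, lbr = 1)), "ratio")
  expect_error(phantom_spec(spheres = data.frame(
    x = 30, y = 30, z = 30, diameter = -2, lbr = 4)), "diameter")
})

test_that("gaussian blur preserves mass and spreads a point source", {
  a <- array(0, c(21, 21, 21)); a[11, 11, 11] <- 1000
  b <- gaussian_blur(a, c(2, 2, 2), fwhm = 6)
  expect_equal(sum(b), 1000, tolerance = 1e-6)
  expect_lt(max(b), 1000)
  # half-maximum width along an axis ~ FWHM
  prof <- b[, 11, 11]
  half <- which(prof >= max(prof) / 2)
  width_mm <- (max(half) - min(half)) * 2
  expect_lt(abs(width_mm - 6), 2.1)
})

test_that("noise-free thresholds between background and lesion are exact", {
  ph <- sphere_phantom(diameter = 28, lbr = 4)
  voi <- ellipsoid_voi(phantom_center(ph), c(24, 24, 24))
  truth <- ph$truth[[1]]$mask
  for (th in c(1.5, 2.0, 3.9))
    expect_identical(segment_absolute_suv(ph$image, voi, th)$mask, truth)
})

test_that("recovery experiment records failures instead of aborting", {
  tab <- run_recovery_experiment(diameters = 22, lbrs = 4, seeds = 1,
                                 methods = c("mo-pet", "nonsense"),
                                 psf_fwhm = 0, noise_coef = 0)
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$ratio[tab$method == "nonsense"]))
  expect_match(tab$error[tab$method == "nonsense"], "unknown method")
  expect_false(is.na(tab$ratio[tab$method == "mo-pet"]))
  summ <- summarize_recovery(tab)
  expect_equal(summ$n_failed[summ$method == "nonsense"], 1L)
})

test_that("30% SUVmax floods the VOI at low lesion-to-background ratio", {
  # at LBR 2 the 30% cut falls below the background level, so the whole
  # VOI is selected: a gross overestimate, the reverse of the
  # underestimate seen at high SUVmax
  tab <- run_recovery_experiment(diameters = 28, lbrs = 2, seeds = 1:3,
                                 methods = "percent-30")
  expect_true(all(tab$ratio > 3))
})
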