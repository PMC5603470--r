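# Segmentation methods on phantoms with known ground truth.

test_that("noise-free sphere is recovered exactly by all threshold methods", {
  ph <- sphere_phantom(diameter = 22, lbr = 8)
  truth <- ph$truth[[1]]$mask
  voi <- ellipsoid_voi(phantom_center(ph), c(21, 21, 21))
  mo <- segment_mo_pet(ph$image, voi, K = 2)
  expect_identical(mo$mask$mask, truth)
  expect_gt(mo$suv_cut, 1); expect_lt(mo$suv_cut, 8)
  expect_identical(segment_absolute_suv(ph$image, voi, 2.0)$mask, truth)
  expect_identical(segment_percent_suvmax(ph$image, voi, 0.30)$mask, truth)
})

test_that("absolute threshold is inclusive and flags empty masks", {
  a <- array(0, c(3, 3, 3)); a[1, 2, 2] <- 1.9; a[2, 2, 2] <- 2.0
  a[3, 2, 2] <- 2.1
  img <- suv_image(a, spacing = c(2, 2, 2))
  voi <- ellipsoid_voi(c(2, 2, 2), c(10, 10, 10))
  m <- segment_absolute_suv(img, voi, 2.0)
  expect_equal(sum(m$mask), 2L)
  expect_true(m$mask[2, 2, 2] && m$mask[3, 2, 2])
  expect_warning(me <- segment_absolute_suv(img, voi, 5.0), "empty")
  expect_equal(sum(me$mask), 0L)
  # brute-force scan oracle on a random phantom
  ph <- sphere_phantom(diameter = 17, lbr = 4, psf_fwhm = 6,
                       noise_coef = 0.1, seed = 5)
  voi2 <- ellipsoid_voi(phantom_center(ph), c(20, 20, 20))
  vm <- voi_to_mask(voi2, ph$image)$mask
  m2 <- segment_absolute_suv(ph$image, voi2, 2.0)
  expect_identical(m2$mask, vm & ph$image$data >= 2.0)
})

test_that("percent-SUVmax cut and limiting behavior", {
  a <- array(1, c(5, 5, 5)); a[3, 3, 3] <- 10; a[2, 3, 3] <- 3
  img <- suv_image(a, spacing = c(2, 2, 2))
  voi <- ellipsoid_voi(c(4, 4, 4), c(20, 20, 20))
  m <- segment_percent_suvmax(img, voi, 0.30)
  expect_equal(m$params$suv_cut, 3.0)           # 30% of SUVmax 10
  expect_equal(sum(m$mask), 2L)
  # fraction near 1: only voxels tied with SUVmax survive
  a2 <- array(1, c(5, 5, 5)); a2[c(32, 94)] <- 7
  img2 <- suv_image(a2, spacing = c(2, 2, 2))
  m2 <- segment_percent_suvmax(img2, voi, 0.999)
  expect_equal(which(m2$mask), c(32L, 94L))
  expect_error(segment_percent_suvmax(img, voi, 1.2), "between 0 and 1")
})

test_that("threshold-mask nesting (property)", {
  ph <- sphere_phantom(diameter = 22, lbr = 4, psf_fwhm = 6,
                       noise_coef = 0.1, seed = 9)
  voi <- ellipsoid_voi(phantom_center(ph), c(22, 22, 22))
  set.seed(12)
  for (rep in 1:10) {
    th <- sort(runif(2, 1.2, 3.5))
    ma <- suppressWarnings(segment_absolute_suv(ph$image, voi, th[1])$mask)
    mb <- suppressWarnings(segment_absolute_suv(ph$image, voi, th[2])$mask)
    expect_true(all(ma[mb]))                    # mask(b) subset of mask(a)
    fr <- sort(runif(2, 0.2, 0.9))
    m1 <- suppressWarnings(segment_percent_suvmax(ph$image, voi, fr[1])$mask)
    m2 <- suppressWarnings(segment_percent_suvmax(ph$image, voi, fr[2])$mask)
    expect_true(all(m1[m2]))
  }
})

test_that("percent method is scale invariant, absolute method is not", {
  ph <- sphere_phantom(diameter = 22, lbr = 4, psf_fwhm = 6,
                       noise_coef = 0.1, seed = 31)
  voi <- ellipsoid_voi(phantom_center(ph), c(22, 22, 22))
  scaled <- suv_image(ph$image$data * 2.7, ph$image$spacing,
                      ph$image$origin, ph$image$direction)
  expect_identical(segment_percent_suvmax(ph$image, voi, 0.4)$mask,
                   segment_percent_suvmax(scaled, voi, 0.4)$mask)
  expect_false(identical(segment_absolute_suv(ph$image, voi, 2.0)$mask,
                         segment_absolute_suv(scaled, voi, 2.0)$mask))
})

test_that("MO-PET connected-component filter drops disjoint hot spots", {
  center <- c(63, 63, 63)
  spec <- phantom_spec(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                       background_suv = 1,
                       spheres = data.frame(
                         x = c(43, 85), y = center[2], z = center[3],
                         diameter = c(20, 14), lbr = c(8, 6)),
                       psf_fwhm = 0, noise_coef = 0, seed = 1)
  ph <- generate_phantom(spec)
  voi <- ellipsoid_voi(center, c(45, 25, 25))   # covers both spheres
  res <- segment_mo_pet(ph$image, voi, K = 2)
  # only the component containing the SUVmax voxel (the LBR-8 sphere)
  expect_identical(res$mask$mask, ph$truth[[1]]$mask)
  res2 <- segment_mo_pet(ph$image, voi, K = 2, connected = FALSE)
  expect_identical(res2$mask$mask,
                   ph$truth[[1]]$mask | ph$truth[[2]]$mask)
})

test_that("MO-PET mask monotonicity: kept voxels are the hottest in-VOI", {
  ph <- sphere_phantom(diameter = 22, lbr = 4, psf_fwhm = 6,
                       noise_coef = 0.1, seed = 13)
  voi <- ellipsoid_voi(phantom_center(ph), c(21, 21, 21))
  res <- segment_mo_pet(ph$image, voi, K = 2, connected = FALSE)
  inside <- voi_to_mask(voi, ph$image)$mask
  kept <- ph$image$data[res$mask$mask]
  dropped <- ph$image$data[inside & !res$mask$mask]
  expect_gte(min(kept), res$suv_cut)
  expect_lt(max(dropped), res$suv_cut)
})

test_that("degenerate VOI contents error, never a silent empty mask", {
  img <- suv_image(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
  voi <- ellipsoid_voi(c(9, 9, 9), c(8, 8, 8))
  expect_error(segment_mo_pet(img, voi), "degenerate")
  expect_error(segment_gradient(img, voi), "flat")
})

test_that("gradient method finds a hard sphere edge within a voxel shell", {
  ph <- sphere_phantom(diameter = 22, lbr = 8)
  voi <- ellipsoid_voi(phantom_center(ph), c(21, 21, 21))
  g <- segment_gradient(ph$image, voi, smoothing_fwhm = 0)
  vol <- mask_volume(g)
  r_cm <- 1.1
  shell <- 4 * pi * r_cm^2 * 0.2                # one 2 mm voxel shell
  expect_lt(abs(vol - 4 / 3 * pi * r_cm^3), shell)
  expect_identical(g$method, "gradient (generic)")
})

test_that("gradient recovers blurred sphere diameter within 2 voxels", {
  devs <- vapply(1:5, function(s) {
    ph <- sphere_phantom(diameter = 22, lbr = 8, psf_fwhm = 6,
                         noise_coef = 0.1, seed = s,
                         shape = c(48, 48, 48))
    voi <- ellipsoid_voi(phantom_center(ph), c(21, 21, 21))
    g <- segment_gradient(ph$image, voi, smoothing_fwhm = 0)
    d_rec <- 2 * (3 * mask_volume(g) / (4 * pi))^(1 / 3) * 10  # mm
    abs(d_rec - 22)
  }, numeric(1))
  expect_lt(max(devs), 4)                       # 2 voxels at 2 mm spacing
})
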