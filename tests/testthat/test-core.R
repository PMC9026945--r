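test_that("seed correction finds the window maximum with deterministic ties", {
  ## unique global maximum inside the search window
  v <- array(0, c(11, 11, 11)); v[6, 6, 6] <- 10
  vol <- volume3d(v)
  cs <- correct_seed(vol, seed_point(5, 5, 5), window_radius = 3)
  expect_equal(c(cs$i, cs$j, cs$k), c(6, 6, 6))
  expect_identical(cs$kind, "corrected")

  ## constant volume: lowest (i, j, k) lexicographically within the window
  cvol <- volume3d(array(7, c(11, 11, 11)))
  cs2 <- correct_seed(cvol, seed_point(5, 6, 7), window_radius = 3)
  expect_equal(c(cs2$i, cs2$j, cs2$k), c(2, 3, 4))

  expect_error(correct_seed(vol, seed_point(12, 1, 1)),
               class = "hsp_contract_error")
})

test_that("seed correction and initial threshold match a brute-force window scan", {
  set.seed(42)
  dims <- c(15L, 15L, 15L)
  vol <- volume3d(array(rnorm(prod(dims)), dim = dims))
  for (rep in 1:100) {
    ms <- random_seed_point(dims)
    r <- 3L
    ir <- max(1, ms$i - r):min(dims[1], ms$i + r)
    jr <- max(1, ms$j - r):min(dims[2], ms$j + r)
    kr <- max(1, ms$k - r):min(dims[3], ms$k + r)
    sub <- vol$data[ir, jr, kr, drop = FALSE]
    cs <- correct_seed(vol, ms, r)
    expect_equal(vol$data[cs$i, cs$j, cs$k], max(sub))
    expect_true(cs$i %in% ir && cs$j %in% jr && cs$k %in% kr)
    expect_equal(initial_threshold(vol, cs, r),
                 max(vol$data[max(1, cs$i - r):min(dims[1], cs$i + r),
                              max(1, cs$j - r):min(dims[2], cs$j + r),
                              max(1, cs$k - r):min(dims[3], cs$k + r)]))
  }
})

test_that("Gaussian smoothing: identity at sigma 0, constant invariance, kernel oracle", {
  vol <- volume3d(array(rnorm(9^3), dim = c(9, 9, 9)))
  expect_identical(smooth_volume(vol, 0)$data, vol$data)

  cvol <- volume3d(array(5, c(9, 9, 9)))
  expect_equal(smooth_volume(cvol, 1.5)$data, cvol$data, tolerance = 1e-9)

  ## unit impulse: the centre of the smoothed volume must equal the central
  ## weight of the explicit 3D kernel (sigma 0.5 -> radius 2)
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm <- smooth_volume(volume3d(imp), 0.5)
  k3 <- oracle_gaussian_kernel3(0.5, radius = 2)
  expect_equal(sm$data[11, 11, 11], k3[3, 3, 3], tolerance = 1e-12)
  ## and the full neighbourhood reproduces the kernel
  expect_equal(sm$data[9:13, 9:13, 9:13], k3, tolerance = 1e-12)

  expect_error(smooth_volume(vol, -1), class = "hsp_contract_error")
})

test_that("muscle mean is the plain average of original intensities over the ROI", {
  v <- array(0, c(6, 6, 6))
  v[1:3, 1:3, 1:3] <- 120
  vol <- volume3d(v)
  roi <- array(FALSE, c(6, 6, 6)); roi[1:3, 1:3, 1:3] <- TRUE
  expect_equal(muscle_mean(vol, mask3d(roi)), 120)

  v2 <- array(0, c(6, 6, 6)); v2[1, 1, 1] <- 100; v2[2, 1, 1] <- 140
  roi2 <- array(FALSE, c(6, 6, 6)); roi2[1:2, 1, 1] <- TRUE
  expect_equal(muscle_mean(volume3d(v2), mask3d(roi2)), 120)

  set.seed(7)
  rv <- array(rnorm(6^3, 100, 15), c(6, 6, 6))
  rroi <- array(runif(6^3) < 0.3, c(6, 6, 6))
  expect_equal(muscle_mean(volume3d(rv), mask3d(rroi)),
               sum(rv[rroi]) / sum(rroi))

  expect_error(muscle_mean(vol, mask3d(array(FALSE, c(6, 6, 6)))),
               class = "hsp_contract_error")
})

test_that("HSP thresholding keeps plaque voxels strictly above coefficient x muscle mean", {
  v <- array(0, c(5, 5, 5))
  v[1, 1, 1] <- 120; v[2, 1, 1] <- 131; v[3, 1, 1] <- 200
  pm <- array(FALSE, c(5, 5, 5)); pm[1:3, 1, 1] <- TRUE
  out <- segment_hsp(volume3d(v), mask3d(pm), muscle_mean = 100,
                     coefficient = 1.3)
  expect_equal(out$threshold, 130)
  expect_equal(sum(out$mask$data), 2)
  expect_true(out$mask$data[2, 1, 1] && out$mask$data[3, 1, 1])
  expect_false(out$mask$data[1, 1, 1])

  ## threshold above the plaque maximum empties the mask
  hi <- segment_hsp(volume3d(v), mask3d(pm), muscle_mean = 100,
                    coefficient = 2.5)
  expect_equal(sum(hi$mask$data), 0)

  ## random case equals the element-wise comparison done directly
  set.seed(11)
  rv <- array(runif(7^3, 80, 220), c(7, 7, 7))
  rpm <- array(runif(7^3) < 0.4, c(7, 7, 7))
  got <- segment_hsp(volume3d(rv), mask3d(rpm), 100, 1.3)
  expect_identical(got$mask$data, rpm & (rv > 130))
  expect_true(all(!got$mask$data | rpm))   # containment
})

test_that("volume computation: voxel arithmetic and slice-area convention agree", {
  one <- array(FALSE, c(4, 4, 4)); one[2, 2, 2] <- TRUE
  m <- mask3d(one, spacing = c(0.45, 0.45, 0.9))
  expect_identical(compute_volume(m, method = "voxel_sum"), 0.45 * 0.45 * 0.9)
  expect_equal(compute_volume(m, method = "voxel_sum"), 0.18225)
  expect_equal(compute_volume(mask3d(array(FALSE, c(4, 4, 4)))), 0)

  set.seed(3)
  for (rep in 1:20) {
    rm <- mask3d(array(runif(6 * 5 * 7) < 0.5, c(6, 5, 7)),
                 spacing = runif(3, 0.2, 2))
    vs <- compute_volume(rm, method = "voxel_sum")
    sa <- compute_volume(rm, method = "slice_area")
    expect_equal(vs, sa, tolerance = 1e-9)
  }
})
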