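test_that("sharpening normalises constants to one and cancels global gain", {
  st <- voxel_stack(array(3.7, c(12, 12, 4)), c(0.5, 0.5, 0.5))
  out <- sharpen_normalize(st, window_um = 2)
  expect_equal(unname(out$data), array(1, c(12, 12, 4)), tolerance = 1e-12)

  set.seed(4)
  base <- array(runif(12 * 12 * 4, 0.5, 1.5), c(12, 12, 4))
  g1 <- sharpen_normalize(voxel_stack(base, c(0.5, 0.5, 0.5)), 2)
  g2 <- sharpen_normalize(voxel_stack(7 * base, c(0.5, 0.5, 0.5)), 2)
  expect_equal(g1$data, g2$data, tolerance = 1e-10)
  # a z-dependent global gain cancels plane-wise (floor guard off so the
  # identity is exact)
  gz <- sweep(base, 3, c(1, 0.8, 0.6, 0.4), `*`)
  g1f <- sharpen_normalize(voxel_stack(base, c(0.5, 0.5, 0.5)), 2,
                           mean_floor_frac = 0)
  g3 <- sharpen_normalize(voxel_stack(gz, c(0.5, 0.5, 0.5)), 2,
                          mean_floor_frac = 0)
  expect_equal(g3$data, g1f$data, tolerance = 1e-10)
})

test_that("sharpening matches an independent plain-loop sliding mean", {
  set.seed(5)
  plane <- matrix(runif(25, 0.2, 1), 5, 5)
  plane[3, 3] <- 5 # single bright pixel
  arr <- array(plane, c(5, 5, 1))
  st <- voxel_stack(arr, c(1, 1, 1))
  out <- sharpen_normalize(st, window_um = 3, mean_floor_frac = 0)
  expect_equal(out$data[, , 1], plane / oracle_sliding_mean(plane, 3),
               tolerance = 1e-10)
  expect_error(sharpen_normalize(st, window_um = 50), "larger than")
})

test_that("sheetness formula matches direct eigenvalue substitution", {
  expect_equal(sheetness_from_eigenvalues(-2, 0, 0), 2)
  expect_equal(sheetness_from_eigenvalues(-2, -2, -2), 2 * exp(-0.5),
               tolerance = 1e-12)
  # non-negative eigenvalue d1 gives zero response
  expect_equal(sheetness_from_eigenvalues(0, 1, 2), 0)
  expect_equal(sheetness_from_eigenvalues(1, 2, 3), 0)
})

test_that("closed-form Hessian eigenvalues match the per-voxel eigen solver", {
  set.seed(6)
  arr <- array(runif(14 * 12 * 10), c(14, 12, 10))
  arr <- cytovox:::gauss_blur3d(arr, 0.6, c(0.5, 0.5, 0.5))
  got <- cytovox:::hessian_eigenvalues(arr, c(0.5, 0.5, 0.5))
  want <- oracle_hessian_eigen(arr, c(0.5, 0.5, 0.5))
  expect_equal(got$d1, want$d1, tolerance = 1e-8)
  expect_equal(got$d2, want$d2, tolerance = 1e-8)
  expect_equal(got$d3, want$d3, tolerance = 1e-8)
})

test_that("sheet enhancement peaks on a bright slab, weakly on a blob", {
  d <- c(21, 21, 21); sp <- c(0.5, 0.5, 0.5)
  z0 <- 11L
  zs <- (seq_len(d[3]) - z0) * sp[3]
  slab <- array(rep(exp(-zs^2 / (2 * 0.5^2)), each = d[1] * d[2]), dim = d)
  resp <- sheetness(voxel_stack(slab, sp), 0.5)$data
  # argmax over z sits on the slab plane (+- 1 voxel) away from borders
  for (x in c(8, 11, 14)) {
    prof <- resp[x, 11, ]
    expect_lte(abs(which.max(prof) - z0), 1)
  }
  cc <- cytovox:::box_coords(c(0, 0, 0), d - 1)
  r2 <- colSums((t(sweep(cc, 2, sp, `*`)) - 5)^2)
  blob <- array(exp(-r2 / (2 * 0.5^2)), dim = d)
  resp_blob <- sheetness(voxel_stack(blob, sp), 0.5)$data
  expect_lte(resp_blob[11, 11, 11], max(resp) / 3)
})

test_that("membrane-route guide is high on boundaries, zero for flat input", {
  ph <- ph_small()
  guide <- guide_small()
  expect_true(all(guide$data >= 0 & guide$data <= 1))
  L <- ph$truth$labels$labels
  bnd <- cytovox:::.label_boundaries(L)
  interior <- L > 0 & cytovox:::edt3d(L == 0, ph$dna$spacing) > 1.2
  expect_gt(mean(guide$data[bnd]), 3 * mean(guide$data[interior]))
  # deterministic
  g2 <- make_guide_worm(ph$membrane, 4, 0.25)
  expect_identical(guide$data, g2$data)
  # constant image has no structure
  flat <- voxel_stack(array(1, c(16, 16, 8)), c(0.5, 0.5, 0.5))
  expect_true(all(make_guide_worm(flat, 3, 0.5)$data == 0))
})

test_that("embryo gain model recovers known coefficients", {
  set.seed(8)
  cen <- cbind(runif(40, 0, 20), runif(40, 0, 15), runif(40, 0, 8))
  cf <- c(c1 = -0.05, c2 = 0.8, c3 = 0.5, c4 = 30)
  m <- exp(cf[1] * cen[, 3]) * (cf[2] * cen[, 1] + cf[3] * cen[, 2] + cf[4])
  m <- m * (1 + rnorm(40, 0, 0.01))
  fit <- cytovox:::.fit_embryo_gain(cen, m)
  expect_false(fit$fallback)
  expect_equal(fit$coef, unname(cf), tolerance = 0.05)
  # constant means give the constant model with threshold m0 * k
  m0 <- rep(12, 10)
  fitc <- cytovox:::.fit_embryo_gain(cen[1:10, ], m0)
  pred <- exp(fitc$coef[1] * cen[1:10, 3]) *
    (fitc$coef[2] * cen[1:10, 1] + fitc$coef[3] * cen[1:10, 2] + fitc$coef[4])
  expect_equal(pred, m0, tolerance = 1e-3)
})

test_that("embryo guide handles degenerate inputs per contract", {
  dna <- voxel_stack(array(runif(16 * 16 * 8), c(16, 16, 8)), c(0.5, 0.5, 0.5))
  dets <- detection_set(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_error(make_guide_embryo(dna, dets), "at least 4")
  # all-background image: every voxel below threshold -> constant guide
  lowdna <- voxel_stack(array(0.001, c(16, 16, 8)) +
                          array(runif(16 * 16 * 8, 0, 1e-5), c(16, 16, 8)),
                        c(0.5, 0.5, 0.5))
  dets4 <- detection_set(c(1, 6, 1, 6), c(1, 1, 6, 6), c(1, 3, 2, 3))
  g <- suppressWarnings(make_guide_embryo(lowdna, dets4, k = 1e6))
  expect_lt(diff(range(g$data)), 1e-6)
})
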