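test_that("window features match the plain-loop HOG reference", {
  set.seed(10)
  arr <- array(runif(24 * 20 * 16), c(24, 20, 16))
  st <- voxel_stack(arr, c(1, 1, 1))
  cfg <- detector_config(cell_radius_um = 4, window_um = 16, grid = 4L)
  for (cen in list(c(12, 10, 8), c(3, 3, 3), c(23, 19, 15))) {
    got <- extract_window_features(st, cen, 1, cfg)
    want <- oracle_window_features(arr, cen, 16, 4, 18, 1)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # scaled window
  got <- extract_window_features(st, c(12, 10, 8), 1.4, cfg)
  want <- oracle_window_features(arr, c(12, 10, 8), 16, 4, 18, 1.4)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("constant windows give zero histograms; ramps fill one orientation", {
  cfg <- detector_config(cell_radius_um = 4, window_um = 8, grid = 2L)
  st <- voxel_stack(array(2.5, c(16, 16, 16)), c(1, 1, 1))
  f <- extract_window_features(st, c(8, 8, 8), 1, cfg)
  expect_equal(f[1], 2.5)
  expect_true(all(f[-1] == 0))

  ramp <- array(rep(seq_len(16), times = 16 * 16), c(16, 16, 16)) # I = x
  fr <- extract_window_features(voxel_stack(ramp, c(1, 1, 1)), c(8, 8, 8), 1, cfg)
  blk <- matrix(fr[2:(1 + 4 * 19)], nrow = 19) # xy block, 4 sub-windows
  hists <- blk[1:18, ]
  # all gradient mass in the 0-degree bin
  expect_true(all(hists[1, ] > 0))
  expect_true(all(hists[-1, ] == 0))
  # rotating the window 90 degrees moves the mass to the 90-degree bin
  ramp_y <- aperm(ramp, c(2, 1, 3))
  fy <- extract_window_features(voxel_stack(ramp_y, c(1, 1, 1)), c(8, 8, 8), 1, cfg)
  blky <- matrix(fy[2:(1 + 4 * 19)], nrow = 19)
  bin90 <- 10 # orientation pi/2 falls in bin floor(0.5 * 18) + 1
  expect_true(all(blky[bin90, ] > 0))
  expect_true(all(blky[setdiff(1:18, bin90), ] == 0))
})

test_that("greedy suppression equals the quadratic oracle", {
  set.seed(11)
  n <- 100
  dets <- detection_set(runif(n, 0, 20), runif(n, 0, 10), runif(n, 0, 10),
                        score = rnorm(n))
  sup <- nonmax_suppress(dets, 2)
  kept <- oracle_nonmax(as.data.frame(dets), 2)
  expect_equal(sup$x_um, dets$x_um[kept])
  # two detections half a radius apart: only the higher survives
  two <- detection_set(c(0, 0.5), c(0, 0), c(0, 0), score = c(2, 1))
  expect_equal(nrow(nonmax_suppress(two, 1)), 1L)
  expect_equal(nonmax_suppress(two, 1)$score, 2)
  # all pairwise farther than the radius: unchanged
  far <- detection_set(c(0, 5, 10), c(0, 0, 0), c(0, 0, 0), score = 3:1)
  expect_equal(nrow(nonmax_suppress(far, 2)), 3L)
})

test_that("mining against a negative pool equals training on the full pool", {
  set.seed(12)
  n <- 60; p <- 40
  X_pos <- matrix(rnorm(n * p, mean = 1.2), n, p)
  X_neg <- matrix(rnorm(140 * p, mean = -0.2), 140, p)
  mined <- cytovox:::svm_mine(X_pos, X_neg, cost = 1)
  full <- cytovox:::.svm_fit(rbind(X_pos, X_neg),
                             c(rep(1, n), rep(-1, 140)), cost = 1)
  cosine <- sum(mined$w * full$w) / sqrt(sum(mined$w^2) * sum(full$w^2))
  expect_gt(cosine, 0.999)
})

test_that("a linear SVM separates separable clusters", {
  set.seed(13)
  X <- rbind(matrix(rnorm(50 * 5, 3), 50, 5), matrix(rnorm(50 * 5, -3), 50, 5))
  y <- c(rep(1, 50), rep(-1, 50))
  fit <- cytovox:::.svm_fit(X, y, cost = 1)
  sc <- as.numeric(X %*% fit$w) - fit$rho
  expect_true(min(sc[y == 1]) > max(sc[y == -1]))
})

test_that("scanning is translation-covariant and tau = +Inf empties the set", {
  set.seed(14)
  arr <- array(runif(30 * 20 * 16), c(30, 20, 16))
  cfg <- detector_config(cell_radius_um = 1.5, window_um = 6, grid = 2L,
                         n_scales = 1L, scale_range = c(1, 1))
  flen <- 1 + 2 * cfg$grid^2 * (cfg$nbins + 1)
  set.seed(15)
  model <- structure(list(w = rnorm(flen), rho = 0, config = cfg),
                     class = "vox_detector")
  st <- voxel_stack(arr, c(1, 1, 1))
  expect_equal(nrow(scan_detect(st, model, tau = Inf)), 0L)
  d1 <- scan_detect(st, model, tau = 2, suppress = FALSE)
  shifted <- array(0, dim = dim(arr) + c(3, 0, 0))
  shifted[4:33, , ] <- arr
  d2 <- scan_detect(voxel_stack(shifted, c(1, 1, 1)), model, tau = 2,
                    suppress = FALSE)
  # interior detections shift by exactly the translation
  inner1 <- d1[d1$x_um > 6 & d1$x_um < 24, ]
  inner2 <- d2[d2$x_um > 9 & d2$x_um < 27, ]
  expect_true(all(paste(inner1$x_um + 3, inner1$y_um, inner1$z_um) %in%
                  paste(inner2$x_um, inner2$y_um, inner2$z_um)))
})

test_that("rescaling intensities does not change window ranking under zero brightness weight", {
  set.seed(16)
  arr <- array(runif(20 * 16 * 12), c(20, 16, 12))
  cfg <- detector_config(cell_radius_um = 2, window_um = 8, grid = 2L,
                         n_scales = 1L, scale_range = c(1, 1))
  flen <- 1 + 2 * cfg$grid^2 * (cfg$nbins + 1)
  w <- rnorm(flen)
  # zero out brightness and the (scale-carrying) normalisation factors so the
  # score depends only on the scale-invariant normalised histograms
  norm_idx <- c(1, 1 + seq_len(2 * cfg$grid^2) * (cfg$nbins + 1))
  w[norm_idx] <- 0
  model <- structure(list(w = w, rho = 0, config = cfg), class = "vox_detector")
  d1 <- scan_detect(voxel_stack(arr, c(1, 1, 1)), model, tau = -Inf,
                    suppress = FALSE, max_detections = 100000L)
  d2 <- scan_detect(voxel_stack(2 * arr, c(1, 1, 1)), model, tau = -Inf,
                    suppress = FALSE, max_detections = 100000L)
  key1 <- order(d1$x_um, d1$y_um, d1$z_um)
  key2 <- order(d2$x_um, d2$y_um, d2$z_um)
  expect_equal(rank(d1$score[key1]), rank(d2$score[key2]), tolerance = 1e-8)
})
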