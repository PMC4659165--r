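test_that("detection matching implements the nearest-in-radius rule", {
  truth <- rbind(c(0, 0, 0), c(10, 0, 0))
  # identical detections: all TP
  mr <- match_detections(truth, truth, 1.5)
  expect_equal(mr$n_tp, 2L); expect_equal(mr$precision, 1); expect_equal(mr$recall, 1)
  # one truth, two detections at 0.5 and 1.0 um: nearer is TP, farther FP
  dets <- rbind(c(0.5, 0, 0), c(1, 0, 0))
  mr2 <- match_detections(dets, rbind(c(0, 0, 0)), 1.5)
  expect_equal(mr2$tp, c(TRUE, FALSE))
  expect_equal(mr2$n_fp, 1L)
  expect_equal(mr2$n_fn, 0L)
  # truth with nothing in radius is a false negative
  mr3 <- match_detections(rbind(c(5, 0, 0)), rbind(c(0, 0, 0)), 1.5)
  expect_equal(mr3$n_fn, 1L)
})

test_that("random matching instances agree with the exhaustive oracle", {
  set.seed(20)
  for (rep in 1:5) {
    truth <- cbind(runif(20, 0, 30), runif(20, 0, 10), runif(20, 0, 10))
    pts <- cbind(runif(25, 0, 30), runif(25, 0, 10), runif(25, 0, 10))
    got <- match_detections(pts, truth, 1.5)
    want <- oracle_match(pts, truth, 1.5)
    expect_equal(got$n_tp, want$n_tp)
    expect_equal(got$n_fp, want$n_fp)
    expect_equal(got$n_fn, want$n_fn)
  }
})

test_that("average precision reproduces the hand-computed sweep", {
  # 3 truths; ranked detections TP, FP, TP, TP -> AP = 0.8056
  truth <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  dets <- detection_set(c(0, 40, 10, 20), rep(0, 4), rep(0, 4),
                        score = c(4, 3, 2, 1))
  res <- average_precision(dets, truth)
  expect_equal(res$ap, 1 / 3 * (1 + 2 / 3 + 3 / 4), tolerance = 1e-12)
  # perfect ranking gives AP = 1, garbage gives 0
  perfect <- detection_set(c(0, 10, 20), rep(0, 3), rep(0, 3), score = 3:1)
  expect_equal(average_precision(perfect, truth)$ap, 1)
  junk <- detection_set(c(40, 50), c(0, 0), c(0, 0), score = c(2, 1))
  expect_equal(average_precision(junk, truth)$ap, 0)
  expect_error(average_precision(perfect, truth[0, , drop = FALSE]), "empty truth")
})

test_that("AP is invariant to strictly monotone score transformations", {
  set.seed(21)
  truth <- cbind(runif(10, 0, 20), runif(10, 0, 8), runif(10, 0, 8))
  dets <- detection_set(runif(15, 0, 20), runif(15, 0, 8), runif(15, 0, 8),
                        score = rnorm(15))
  a1 <- average_precision(dets, truth)$ap
  dets2 <- dets
  dets2$score <- exp(3 * dets$score) + 7
  expect_equal(average_precision(dets2, truth)$ap, a1, tolerance = 1e-12)
})

test_that("Jaccard handles identity, partial overlap, disjoint, empty", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- TRUE
  expect_equal(jaccard(a, b), 4 / 12) # 8-voxel cubes sharing 4 voxels
  d <- array(FALSE, c(4, 4, 4)); d[4, 4, 4] <- TRUE
  expect_equal(jaccard(a, d), 0)
  expect_warning(val <- jaccard(array(FALSE, c(2, 2, 2)),
                                array(FALSE, c(2, 2, 2))), "empty")
  expect_equal(val, 0)
  expect_error(jaccard(a, array(FALSE, c(3, 3, 3))), "mismatch")
})

test_that("AO is invariant to relabeling and ignores unmatched segments", {
  ph <- ph_clean()
  L <- ph$truth$labels$labels
  perm <- sample(15)
  L2 <- array(0L, dim = dim(L))
  for (i in 1:15) L2[L == i] <- perm[i]
  res <- segmentation_ao(label_volume(L2, ph$dna$spacing), ph$truth$labels)
  expect_equal(res$ao, 1)
  expect_equal(res$precision, 1)
  # an extra spurious segment leaves AO unchanged but lowers precision
  L3 <- L
  L3[1, 1, 1] <- 99L
  res3 <- segmentation_ao(label_volume(L3, ph$dna$spacing), ph$truth$labels)
  expect_equal(res3$ao, 1, tolerance = 1e-6)
  expect_lt(res3$precision, 1)
})

test_that("optimal matching equals exhaustive permutation search on small instances", {
  set.seed(22)
  for (rep in 1:4) {
    A <- array(sample(0:5, 6 * 6 * 4, replace = TRUE), c(6, 6, 4))
    B <- array(sample(0:6, 6 * 6 * 4, replace = TRUE), c(6, 6, 4))
    res <- segmentation_ao(A, B)
    J <- res$jaccard_matrix
    expect_equal(sum(res$matches$jaccard), oracle_assignment_total(J),
                 tolerance = 1e-12)
  }
})

test_that("AO is symmetric up to precision/recall exchange", {
  set.seed(23)
  A <- array(sample(0:4, 5 * 5 * 5, replace = TRUE), c(5, 5, 5))
  B <- array(sample(0:3, 5 * 5 * 5, replace = TRUE), c(5, 5, 5))
  ab <- segmentation_ao(A, B)
  ba <- segmentation_ao(B, A)
  expect_equal(ab$ao, ba$ao, tolerance = 1e-12)
  expect_equal(ab$precision, ba$recall)
  expect_equal(ab$recall, ba$precision)
})
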