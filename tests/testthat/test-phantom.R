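test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(n_cells = 6)
  a <- generate_phantom(spec, seed = 5)
  b <- generate_phantom(spec, seed = 5)
  expect_identical(a$dna$data, b$dna$data)
  expect_identical(a$membrane$data, b$membrane$data)
  expect_identical(a$truth$labels$labels, b$truth$labels$labels)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("true masks are disjoint, contain their centres, and respect spacing", {
  ph <- ph_small()
  L <- ph$truth$labels$labels
  cen <- ph$truth$centers_um
  sp <- ph$truth$labels$spacing
  for (i in seq_len(nrow(cen))) {
    v <- round(cen[i, ] / sp) + 1
    expect_equal(L[v[1], v[2], v[3]], i)
  }
  # pairwise centre distances respect the stated floor
  dmat <- as.matrix(dist(cen))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 1.5)
})

test_that("phase labels, DNA contents and EdU status are mutually consistent", {
  ph <- ph_small()
  cells <- ph$truth$cells
  expect_true(all(cells$content[cells$phase == "G1"] == 2))
  expect_true(all(cells$content[cells$phase %in% c("G2", "M")] == 4))
  s <- cells$content[cells$phase == "S"]
  expect_true(all(s >= 2 & s <= 4))
  expect_identical(cells$edu, cells$phase == "S")
})

test_that("summed raw DNA over true masks recovers contents up to a constant", {
  ph <- ph_clean()
  L <- ph$truth$labels$labels
  sums <- vapply(seq_len(nrow(ph$truth$centers_um)),
                 function(k) sum(ph$dna$data[L == k]), numeric(1))
  ratio <- sums / ph$truth$cells$content
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)
})

test_that("single-cell degenerate phantom has membrane only around the cell", {
  ph <- ph_single()
  L <- ph$truth$labels$labels
  far <- cytovox:::edt3d(L > 0, ph$membrane$spacing) > 2
  expect_lt(max(ph$membrane$data[far]), 1e-3)
  expect_gt(max(ph$membrane$data), 0.9)
})

test_that("seed jitter is uniform in the ball with mean magnitude 3 rho / 4", {
  cen <- matrix(0, 10000, 3)
  out <- jitter_seeds(cen, rho_um = 1, seed = 2)
  disp <- sqrt(rowSums(out^2))
  expect_true(all(disp <= 1))
  expect_equal(mean(disp), 0.75, tolerance = 0.015)
  # rho = 0.5: all displacements bounded by the stated radius
  out5 <- jitter_seeds(cen[1:500, ], rho_um = 0.5, seed = 2)
  expect_true(all(sqrt(rowSums(out5^2)) <= 0.5))
  # rho = 0 leaves centres untouched
  expect_identical(jitter_seeds(cen[1:5, ], 0, seed = 1), cen[1:5, ])
})

test_that("guide degradation follows invert / clamp 0.85 / rescale / tile / multiply", {
  # hand-traced kernel: crop containing {0, 1} -> invert {1, 0} ->
  # clamp {0.85, 0} -> rescale {1, 0}
  arr <- array(0.5, c(8, 8, 4))
  arr[1, 1, 1] <- 0; arr[2, 1, 1] <- 1
  g <- voxel_stack(arr, c(1, 1, 1))
  out <- degrade_guide(g, crop_origin = c(0, 0, 0), crop_size = c(2, 1, 1))
  # kernel K = (x=1: 1, x=2: 0), tiled along x
  expect_equal(out$data[1, 1, 1], 0)         # 0 * 1
  expect_equal(out$data[2, 1, 1], 0)         # 1 * 0
  expect_equal(out$data[3, 2, 2], 0.5)       # 0.5 * 1 (tile repeats)
  expect_equal(out$data[4, 2, 2], 0)         # 0.5 * 0
  # output never exceeds the input
  ph <- guide_small()
  deg <- degrade_guide(ph, crop_size = c(10, 10, 6))
  expect_true(all(deg$data <= ph$data + 1e-12))
  expect_true(all(deg$data >= 0))
  # constant crop is rejected
  flat <- voxel_stack(array(0.3, c(6, 6, 6)), c(1, 1, 1))
  expect_error(degrade_guide(flat, crop_size = c(4, 4, 4)), "constant")
})

test_that("infeasible packing errors out after bounded retries", {
  spec <- phantom_spec(n_cells = 500, mean_radius_um = 2,
                      min_separation_um = 3.2)
  # 500 cells cannot fit: dims are derived from n but separation forbids it
  spec$n_cells <- 500
  spec2 <- phantom_spec(n_cells = 4, arrangement = "scatter",
                        min_separation_um = 40)
  expect_error(generate_phantom(spec2, seed = 1), "infeasible packing")
})
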