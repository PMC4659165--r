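# Benchmark orchestration on phantoms: segmenter comparison under
# clean/degraded guides and seed jitter, and detector learning curves.

#' Run the segmenter comparison grid
#'
#' Generates a phantom, builds the membrane-route guide, and evaluates the
#' three segmenters (active contours, truncated Voronoi, marker-controlled
#' watershed) under each condition: clean guide with seed jitter 0 / 0.5 /
#' 1 um, and an artificially degraded guide. Reports AO, segment precision
#' and recall per condition plus the relative AO decrease against each
#' segmenter's clean/no-jitter baseline.
#'
#' @param spec a [phantom_spec()].
#' @param jitters_um seed jitter radii for the clean guide.
#' @param degraded also run the degraded-guide condition (jitter 0).
#' @param segmenters subset of `c("ac", "voronoi", "watershed")`.
#' @param params [contour_params()] for the active contours; by default the
#'   sub-window margin is 1.2 x the mean cell radius, which bounds how far a
#'   contour can stray through guide defects.
#' @param crop_size degradation kernel crop (voxels); the default is sized
#'   for phantom stacks (the full-stack recipe crops 108 x 108 x 40).
#' @param seed RNG seed.
#' @return Tibble: segmenter, guide, jitter_um, ao, precision, recall,
#'   rel_decrease.
#' @export
run_segmenter_grid <- function(spec = phantom_spec(),
                               jitters_um = c(0, 0.5, 1),
                               degraded = TRUE,
                               segmenters = c("ac", "voronoi", "watershed"),
                               params = NULL,
                               crop_size = c(32L, 16L, 14L),
                               seed = 1L) {
  if (is.null(params))
    params <- contour_params(margin_um = 1.2 * spec$mean_radius_um)
  ph <- generate_phantom(spec, seed = seed)
  sp <- spec$spacing
  # blur scale = the membrane Gaussian sd (half the wall thickness)
  guide <- make_guide_worm(ph$membrane, 2 * spec$mean_radius_um,
                           spec$membrane_um / 2)
  d <- dim(guide$data)
  crop_size <- pmax(pmin(crop_size, d %/% 2L), 4L)
  conds <- data.frame(guide = c(rep("clean", length(jitters_um)),
                                if (degraded) "degraded"),
                      jitter = c(jitters_um, if (degraded) 0))
  guides <- list(clean = guide,
                 degraded = if (degraded) degrade_guide(guide, crop_size = crop_size))
  truth <- ph$truth$labels
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    gname <- conds$guide[ci]
    jit <- conds$jitter[ci]
    seeds <- jitter_seeds(ph$truth$centers_um, jit, seed = sub_seed(seed, 10L + ci))
    # keep jittered seeds inside the stack
    seeds <- pmin(pmax(seeds, 0), matrix((d - 1) * sp, nrow(seeds), 3, byrow = TRUE))
    gd <- guides[[gname]]
    for (sg in segmenters) {
      lab <- switch(sg,
        ac = active_contours(gd, seeds, params),
        voronoi = truncated_voronoi(seeds,
          spec$mean_radius_um + spec$membrane_um / 4, d, sp),
        watershed = marker_watershed(gd, seeds, size_bounds = NULL))
      ev <- segmentation_ao(lab, truth)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        segmenter = sg, guide = gname, jitter_um = jit,
        ao = ev$ao, precision = ev$precision, recall = ev$recall)
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$guide == "clean" & out$jitter_um == 0, c("segmenter", "ao")]
  out$rel_decrease <- 1 - out$ao / base$ao[match(out$segmenter, base$segmenter)]
  out
}

#' Detector learning curve: AP versus number of training phantoms
#'
#' Trains the detector on growing subsets of independently generated
#' training phantoms and evaluates average precision on held-out test
#' phantoms, resampling the subsets.
#'
#' @param spec a [phantom_spec()].
#' @param n_train training-set sizes (numbers of stacks).
#' @param n_test held-out test stacks.
#' @param repeats resampled subsets per size.
#' @param config a [detector_config()].
#' @param seed RNG seed.
#' @return Tibble: n_train, repeat_id, ap.
#' @export
run_detector_learning_curve <- function(spec = phantom_spec(),
                                        n_train = c(1, 2, 4, 8),
                                        n_test = 2L, repeats = 3L,
                                        config = detector_config(
                                          cell_radius_um = spec$mean_radius_um,
                                          stride = c(2L, 2L, 2L)),
                                        seed = 1L) {
  n_pool <- max(n_train)
  train <- lapply(seq_len(n_pool), function(i)
    generate_phantom(spec, seed = sub_seed(seed, 20L + i)))
  test <- lapply(seq_len(n_test), function(i)
    generate_phantom(spec, seed = sub_seed(seed, 50L + i)))
  set.seed(sub_seed(seed, 5L))
  rows <- list()
  for (k in n_train) {
    for (r in seq_len(repeats)) {
      pick <- sample(n_pool, k)
      model <- train_detector(lapply(train[pick], function(p) p$dna),
                              lapply(train[pick], function(p) p$truth$centers_um),
                              config, seed = sub_seed(seed, 100L + k * 10L + r))
      aps <- vapply(test, function(te) {
        dets <- scan_detect(te$dna, model, tau = -Inf)
        average_precision(dets, te$truth$centers_um)$ap
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(n_train = k, repeat_id = r,
                                                  ap = mean(aps))
      if (k == n_pool && r == 1L) break # full pool has a single subset
    }
  }
  do.call(rbind, rows)
}
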