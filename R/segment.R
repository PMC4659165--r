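# Seeded 3-D segmentation: level-set active contours (primary), truncated
# Voronoi and marker-controlled watershed (baselines). All segmenters return
# a `label_volume` whose masks are pairwise disjoint and contain their seed.

#' Active-contour parameters
#'
#' The two-step schedule: a conservative first step (`c2 = -1`, contours are
#' pushed back from edge slopes and stop short of boundaries) followed by a
#' refining second step (`c2 = +1`, contours are pulled onto boundaries).
#' Defaults: `c1 = 0.1`, 650 steps of 0.15 for step 1 and 300 steps of 0.15
#' for step 2.
#'
#' @param c1 curvature weight.
#' @param c2_step1,c2_step2 advection weight per step.
#' @param dt time step.
#' @param n_steps1,n_steps2 step counts.
#' @param band_um narrow-band half-width (micrometres).
#' @param reinit_every signed-distance reinitialisation period (steps).
#' @param init_radius_um initialisation ball radius at each seed.
#' @param margin_um cropped sub-window half-size around each seed (default
#'   2 x the expected cell radius; pass explicitly for other radii).
#' @return List of class `contour_params`.
#' @export
contour_params <- function(c1 = 0.1, c2_step1 = -1, c2_step2 = 1,
                           dt = 0.15, n_steps1 = 650L, n_steps2 = 300L,
                           band_um = 0.6, reinit_every = 150L,
                           init_radius_um = NULL, margin_um = 4) {
  stopifnot(dt > 0, n_steps1 >= 0, n_steps2 >= 0)
  structure(list(c1 = c1, c2_step1 = c2_step1, c2_step2 = c2_step2, dt = dt,
                 n_steps1 = as.integer(n_steps1), n_steps2 = as.integer(n_steps2),
                 band_um = band_um, reinit_every = as.integer(reinit_every),
                 init_radius_um = init_radius_um, margin_um = margin_um),
            class = "contour_params")
}

#' Level-set active-contour segmentation
#'
#' Each seed initialises a small ball; per-cell embeddings evolve in cropped
#' sub-windows under
#' `dphi/dt = -g |grad phi| (1 - c1 k) + c2 grad g . grad phi`
#' (inside-negative convention; `g` is the inverted guide, low at
#' boundaries; `k` the mean curvature), using upwind differencing for the
#' advection term, Godunov differencing for the propagation term, narrow-band
#' updates and periodic signed-distance reinitialisation. Voxels claimed by
#' two cells are frozen for both, so masks never overlap.
#'
#' @param guide guide `voxel_stack` in `[0, 1]` (boundaries high).
#' @param seeds detection table or micrometre matrix of seed centres.
#' @param params a [contour_params()].
#' @param saturation how the speed image `g = 1 - guide/threshold` saturates:
#'   `NULL` (default, for guides whose boundaries already saturate at 1)
#'   uses the guide maximum; `"otsu"` picks the threshold separating
#'   background from boundary responses (for unsaturated guides); a numeric
#'   gives a quantile of the positive guide values.
#' @return A `label_volume`; cell k is seeded from row k of `seeds`.
#' @export
active_contours <- function(guide, seeds, params = contour_params(),
                            saturation = NULL) {
  stopifnot(inherits(guide, "voxel_stack"))
  seeds_um <- if (is.matrix(seeds)) seeds else as.matrix(seeds[, c("x_um", "y_um", "z_um")])
  d <- dim(guide$data)
  sp <- guide$spacing
  if (any(seeds_um < 0) ||
      any(sweep(seeds_um, 2, (d - 1) * sp, `>`)))
    stop("seed outside the guide image")
  v <- .um_to_vox_clamped(seeds_um, sp, d)
  # speed image: low at boundaries; the guide is saturated at the
  # boundary-response level so that speed vanishes on every boundary, not
  # just the globally strongest one
  arr <- guide$data
  pos <- arr[arr > 1e-6 * max(arr)]
  thr <- if (length(pos) == 0) 1
         else if (identical(saturation, "otsu")) otsu_threshold(pos)
         else if (is.numeric(saturation)) quantile(pos, saturation, names = FALSE)
         else max(arr)
  if (!is.finite(thr) || thr <= 0) thr <- max(max(arr), 1e-12)
  lo <- min(arr)
  g <- if (thr - lo <= 0) array(1, dim = d) # structureless guide: full speed
       else 1 - pmin((arr - lo) / (thr - lo), 1)
  init_r <- if (is.null(params$init_radius_um)) 1.01 * min(sp) else params$init_radius_um
  margin <- as.integer(ceiling(params$margin_um / min(sp)))
  lab <- cpp_active_contours(as.numeric(g), d, sp, v,
                             params$c1, params$c2_step1, params$c2_step2,
                             params$dt, params$n_steps1, params$n_steps2,
                             params$band_um, params$reinit_every,
                             init_r, margin)
  label_volume(array(lab, dim = d), sp)
}

#' Truncated Voronoi segmentation
#'
#' Voxel assigned to cell i iff it is nearer (micrometre metric) to seed i
#' than to any other seed and within `r_um` of seed i; exactly equidistant
#' voxels go to the lower cell index. Depends only on the seeds, not on any
#' guide image.
#'
#' @param seeds detection table or micrometre seed matrix (distinct points).
#' @param r_um truncation radius.
#' @param dims volume dimensions in voxels.
#' @param spacing voxel spacing.
#' @return A `label_volume`.
#' @export
truncated_voronoi <- function(seeds, r_um, dims, spacing) {
  stopifnot(r_um > 0)
  seeds_um <- if (is.matrix(seeds)) seeds else as.matrix(seeds[, c("x_um", "y_um", "z_um")])
  if (anyDuplicated(seeds_um)) stop("duplicate seeds")
  n <- nrow(seeds_um)
  lab <- array(0L, dim = dims)
  best <- array(Inf, dim = dims)
  for (i in seq_len(n)) {
    lo <- pmax(floor((seeds_um[i, ] - r_um) / spacing), 0)
    hi <- pmin(ceiling((seeds_um[i, ] + r_um) / spacing), dims - 1)
    if (any(hi < lo)) next
    cc <- box_coords(lo, hi)
    pos <- sweep(cc, 2, spacing, `*`)
    dist <- sqrt(colSums((t(pos) - seeds_um[i, ])^2))
    sel <- dist <= r_um
    if (!any(sel)) next
    cc1 <- cc[sel, , drop = FALSE] + 1L
    flat <- cc1[, 1] + dims[1] * (cc1[, 2] - 1L) + dims[1] * dims[2] * (cc1[, 3] - 1L)
    win <- dist[sel] < best[flat] # strict: ties stay with the lower index
    lab[flat[win]] <- i
    best[flat[win]] <- dist[sel][win]
  }
  label_volume(lab, spacing)
}

#' Marker-controlled watershed segmentation
#'
#' Local minima are imposed at the seed voxels and the guide is flooded
#' (priority flood, 6-connectivity). Segments whose voxel count falls
#' outside `size_bounds` (relative to the median segment volume) are
#' relabelled to background.
#'
#' @param guide guide `voxel_stack` (boundaries high).
#' @param seeds detection table or micrometre seed matrix (distinct points).
#' @param size_bounds keep segments within these fractions of the median
#'   segment voxel count; `NULL` disables the filter.
#' @param background_markers also seed the eight stack corners as a
#'   background basin so the flood does not force empty space into cell
#'   segments.
#' @return A `label_volume`.
#' @export
marker_watershed <- function(guide, seeds, size_bounds = c(0.05, 5),
                             background_markers = TRUE) {
  stopifnot(inherits(guide, "voxel_stack"))
  seeds_um <- if (is.matrix(seeds)) seeds else as.matrix(seeds[, c("x_um", "y_um", "z_um")])
  if (anyDuplicated(seeds_um)) stop("duplicate seeds")
  d <- dim(guide$data)
  v <- .um_to_vox_clamped(seeds_um, guide$spacing, d)
  labs <- seq_len(nrow(v))
  if (isTRUE(background_markers)) {
    corners <- as.matrix(expand.grid(c(0L, d[1] - 1L), c(0L, d[2] - 1L),
                                     c(0L, d[3] - 1L)))
    corners <- corners[!duplicated(rbind(v, corners))[nrow(v) + seq_len(nrow(corners))], ,
                       drop = FALSE]
    v <- rbind(v, corners)
    labs <- c(labs, rep(nrow(seeds_um) + 1L, nrow(corners)))
  }
  lab <- cpp_watershed(as.numeric(guide$data), d, v, labs)
  lab <- array(lab, dim = d)
  lab[lab > nrow(seeds_um)] <- 0L
  if (!is.null(size_bounds)) {
    sizes <- tabulate(lab[lab > 0], nbins = nrow(seeds_um))
    med <- median(sizes[sizes > 0])
    bad <- which(sizes < size_bounds[1] * med | sizes > size_bounds[2] * med)
    if (length(bad)) lab[lab %in% bad] <- 0L
  }
  label_volume(lab, guide$spacing)
}
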