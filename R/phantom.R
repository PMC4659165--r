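# Synthetic 3-D phantoms: tubes (or grids / scatters) of densely packed
# roughly spherical nuclei with peripheral (shell-like) DNA texture,
# phase-dependent chromatin puncta, membrane shells between cells, optional
# EdU channel, z-attenuation and Gaussian/Poisson noise — plus the guide
# degradation and seed-jitter perturbations used for benchmarking.

#' Phantom specification
#'
#' Defines the synthetic imaging conditions: geometry, nuclear texture,
#' noise, attenuation and cell-cycle phase mix. Defaults describe a densely
#' packed tube of ~2 um-radius nuclei imaged at 0.4 um isotropic voxels with
#' shell-like DNA staining, thin membrane walls between neighbours, mild
#' z-attenuation and Gaussian noise giving a signal-to-noise ratio of about 8.
#'
#' @param arrangement `"tube"`, `"grid"` or `"scatter"`.
#' @param n_cells number of nuclei.
#' @param mean_radius_um mean nuclear radius (micrometres).
#' @param radius_jitter fractional sd of per-cell radii.
#' @param spacing voxel spacing (um).
#' @param shell_frac DNA shell thickness as a fraction of the radius.
#' @param puncta named list of puncta counts per phase (ranges).
#' @param membrane_um membrane shell thickness (um).
#' @param noise_sd Gaussian noise sd (intensity units; signal shell ~ 1).
#' @param poisson if TRUE, apply Poisson resampling of the scaled signal.
#' @param psf_sigma_um optical blur sd (um); 0 disables.
#' @param z_attenuation attenuation rate lambda (1/um): intensity x exp(-lambda z).
#' @param axial_gain optional function(d_um) of distance along the tube axis,
#'   multiplying intensity (emulates distal-proximal staining gain).
#' @param phase_mix named fractions for G1/S/G2/M (must sum to 1).
#' @param edu if TRUE, generate an EdU channel labelling S cells.
#' @param min_separation_um minimum distance between generated centres; the
#'   default keeps centres at least 1.5 um apart and scales with radius.
#' @param packing_fill fraction of the tube volume occupied by nuclei
#'   (drives the tube length).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(arrangement = c("tube", "grid", "scatter"),
                         n_cells = 30,
                         mean_radius_um = 2.0,
                         radius_jitter = 0.08,
                         spacing = c(0.25, 0.25, 0.25),
                         shell_frac = 0.35,
                         puncta = list(G1 = c(5, 6), S = c(0, 0),
                                       G2 = c(8, 12), M = c(1, 2)),
                         membrane_um = 0.5,
                         noise_sd = 0.08,
                         poisson = FALSE,
                         psf_sigma_um = 0.15,
                         z_attenuation = 0.0,
                         axial_gain = NULL,
                         phase_mix = c(G1 = 0.25, S = 0.4, G2 = 0.3, M = 0.05),
                         edu = TRUE,
                         min_separation_um = max(1.5, 1.6 * mean_radius_um),
                         packing_fill = 0.55) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_cells >= 1, mean_radius_um > 0, all(spacing > 0),
            shell_frac > 0, shell_frac <= 1,
            all(phase_mix >= 0), abs(sum(phase_mix) - 1) < 1e-8,
            min_separation_um >= 1.5)
  structure(list(arrangement = arrangement, n_cells = n_cells,
                 mean_radius_um = mean_radius_um, radius_jitter = radius_jitter,
                 spacing = spacing, shell_frac = shell_frac, puncta = puncta,
                 membrane_um = membrane_um, noise_sd = noise_sd,
                 poisson = poisson, psf_sigma_um = psf_sigma_um,
                 z_attenuation = z_attenuation, axial_gain = axial_gain,
                 phase_mix = phase_mix, edu = edu,
                 min_separation_um = min_separation_um,
                 packing_fill = packing_fill),
            class = "phantom_spec")
}

# place centres (um) by rejection sampling under a minimum-separation rule
.place_centres <- function(spec, dims_um) {
  n <- spec$n_cells
  r <- spec$mean_radius_um
  centres <- matrix(NA_real_, 0, 3)
  tries <- 0L
  max_tries <- 2000L * n
  while (nrow(centres) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible packing: cannot place ", n,
           " cells with minimum separation ", spec$min_separation_um, " um")
    p <- switch(spec$arrangement,
      tube = {
        ax <- runif(1, r, dims_um[1] - r)
        # uniform in the tube cross-section disc
        repeat {
          u <- runif(2, -1, 1)
          if (sum(u^2) <= 1) break
        }
        rad <- (min(dims_um[2], dims_um[3]) / 2 - r)
        c(ax, dims_um[2] / 2 + u[1] * rad, dims_um[3] / 2 + u[2] * rad)
      },
      scatter = runif(3, r, dims_um - r),
      grid = NULL)
    if (is.null(p)) break
    dmin <- if (nrow(centres) == 0) Inf else
      min(sqrt(colSums((t(centres) - p)^2)))
    ok <- dmin >= spec$min_separation_um
    if (ok && spec$arrangement == "tube" && nrow(centres) > 0)
      # tissue is contiguous: every nucleus must touch the growing cluster
      ok <- dmin <= 1.85 * r
    if (ok) centres <- rbind(centres, p)
  }
  if (spec$arrangement == "grid") {
    pitch <- max(spec$min_separation_um, 2.1 * r)
    per <- ceiling(n^(1 / 3))
    g <- expand.grid(x = seq_len(per), y = seq_len(per), z = seq_len(per))
    g <- g[seq_len(n), , drop = FALSE]
    centres <- as.matrix(g) * pitch - pitch / 2 + r / 2
    centres <- centres + matrix(runif(3 * n, -0.15 * r, 0.15 * r), n, 3)
  }
  unname(centres)
}

.phantom_dims_um <- function(spec) {
  r <- spec$mean_radius_um
  switch(spec$arrangement,
    tube = {
      tube_r <- 2.2 * r
      # tube length set so nuclei fill the stated fraction of the tube
      # volume (densely packed tissue: most neighbouring masks touch)
      vol_cells <- spec$n_cells * 4 / 3 * pi * r^3
      len <- max(8 * r, vol_cells / (pi * tube_r^2 * spec$packing_fill))
      c(len, 2 * tube_r + 2, 2 * tube_r + 2)
    },
    grid = {
      pitch <- max(spec$min_separation_um, 2.1 * r)
      per <- ceiling(spec$n_cells^(1 / 3))
      rep(per * pitch + 2 * r, 3)
    },
    scatter = rep(max(10, (spec$n_cells)^(1 / 3) * 3 * r + 2 * r), 3))
}

#' Generate a synthetic multi-channel phantom with ground truth
#'
#' Produces a DNA channel (peripheral nuclear shell plus phase-dependent
#' chromatin puncta), a membrane channel (bright walls between touching
#' cells and around the tissue), an optional EdU channel (bright in S-phase
#' nuclei), and the complete ground truth: centres, radii, true masks
#' (nearest-centre rule inside each nuclear ball), phase labels, true DNA
#' contents (2 for G1, 4 for G2/M, uniform(2,4) for S) and EdU status.
#' Per-cell summed DNA is proportional to the true content before
#' attenuation and noise. Deterministic given `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed.
#' @return List with elements `dna`, `membrane`, `edu` (voxel stacks; `edu`
#'   NULL if disabled) and `truth` (list: `centers_um`, `radii_um`, `labels`
#'   (a `label_volume`), and a per-cell tibble `cells`).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(sub_seed(seed, 1L))
  sp <- spec$spacing
  dims_um <- .phantom_dims_um(spec)
  dims <- pmax(as.integer(ceiling(dims_um / sp)), 8L)
  dims_um <- dims * sp
  centres <- .place_centres(spec, dims_um)
  n <- nrow(centres)
  radii <- spec$mean_radius_um *
    pmax(0.6, 1 + rnorm(n, 0, spec$radius_jitter))

  phases <- sample(names(spec$phase_mix), n, replace = TRUE,
                   prob = spec$phase_mix)
  content <- ifelse(phases == "G1", 2,
                    ifelse(phases == "S", runif(n, 2, 4), 4))
  edu_pos <- phases == "S"

  # label volume: nearest-centre rule among balls containing the voxel.
  # The cell mask extends halfway into the cytoplasmic gap between the
  # nuclear surface and the membrane ridge: segmentation targets cell
  # boundaries, and DNA (at radius <= r) stays strictly inside the mask.
  r_cell <- radii + spec$membrane_um / 4
  labels <- array(0L, dim = dims)
  bestd <- array(Inf, dim = dims)
  for (i in seq_len(n)) {
    lo <- pmax(floor((centres[i, ] - r_cell[i]) / sp), 0)
    hi <- pmin(ceiling((centres[i, ] + r_cell[i]) / sp), dims - 1)
    cc <- box_coords(lo, hi)
    pos <- sweep(cc, 2, sp, `*`)
    d <- sqrt(colSums((t(pos) - centres[i, ])^2))
    sel <- d <= r_cell[i]
    if (!any(sel)) next
    cc <- cc[sel, , drop = FALSE] + 1L # to 1-based for array indexing
    d <- d[sel]
    flat <- cc[, 1] + dims[1] * (cc[, 2] - 1L) + dims[1] * dims[2] * (cc[, 3] - 1L)
    win <- d < bestd[flat]
    labels[flat[win]] <- i
    bestd[flat[win]] <- d[win]
  }

  # DNA channel: shell + puncta, per-cell sum scaled to content
  dna <- array(0, dim = dims)
  for (i in seq_len(n)) {
    lo <- pmax(floor((centres[i, ] - radii[i]) / sp), 0)
    hi <- pmin(ceiling((centres[i, ] + radii[i]) / sp), dims - 1)
    cc <- box_coords(lo, hi)
    pos <- sweep(cc, 2, sp, `*`)
    rel <- t(pos) - centres[i, ]
    d <- sqrt(colSums(rel^2))
    flat <- (cc[, 1] + 1L) + dims[1] * cc[, 2] + dims[1] * dims[2] * cc[, 3]
    inmask <- labels[flat] == i
    if (!any(inmask)) next
    # chromatin spatial extent grows through the cycle (G1 < S < G2)
    shell_mult <- switch(phases[i], G1 = 0.9, S = 1.15, G2 = 1.4, 1)
    shell_in <- radii[i] * (1 - min(spec$shell_frac * shell_mult, 0.95))
    base <- as.numeric(d >= shell_in & d <= radii[i])
    if (phases[i] == "M") {
      # condensed chromatin: compact bright core, no peripheral shell
      base <- as.numeric(d <= 0.55 * radii[i]) * 2
    }
    val <- base
    # phase-dependent puncta inside the shell
    prange <- spec$puncta[[phases[i]]]
    np <- if (is.null(prange) || prange[2] < 1) 0L else
      prange[1] + sample.int(prange[2] - prange[1] + 1L, 1L) - 1L
    if (np > 0 && phases[i] != "M") {
      for (k in seq_len(np)) {
        # uniform direction, radius inside the shell
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        rad <- runif(1, shell_in, radii[i] * 0.95)
        pc <- centres[i, ] + u * rad
        pd2 <- colSums((t(pos) - pc)^2)
        val <- val + 2.5 * exp(-pd2 / (2 * (0.25 * radii[i])^2))
      }
    } else if (phases[i] == "M") {
      for (k in seq_len(np)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        pc <- centres[i, ] + u * runif(1, 0, 0.3 * radii[i])
        pd2 <- colSums((t(pos) - pc)^2)
        val <- val + 3 * exp(-pd2 / (2 * (0.35 * radii[i])^2))
      }
    }
    val[!inmask] <- 0
    s <- sum(val)
    if (s > 0) val <- val * (content[i] / s) # unit: summed DNA == content
    dna[flat] <- dna[flat] + val
  }
  dna_unit <- mean(dna[dna > 0]) # typical in-shell voxel value
  if (is.finite(dna_unit) && dna_unit > 0) dna <- dna / dna_unit
  # (global rescale keeps per-cell sums proportional to content)

  # membrane channel: analytic Gaussian shells just outside each nuclear
  # surface (a thin cytoplasmic gap separates nucleus and membrane) plus
  # explicit walls on the bisector plane of every overlapping pair, so walls
  # are smooth and hole-free by construction
  sigma_m <- spec$membrane_um / 2
  off <- sigma_m # shell ridge sits this far outside the nuclear surface
  membrane <- array(0, dim = dims)
  reach <- 3 * sigma_m + off
  for (i in seq_len(n)) {
    lo <- pmax(floor((centres[i, ] - radii[i] - reach) / sp), 0)
    hi <- pmin(ceiling((centres[i, ] + radii[i] + reach) / sp), dims - 1)
    cc <- box_coords(lo, hi)
    pos <- sweep(cc, 2, sp, `*`)
    dd <- sqrt(colSums((t(pos) - centres[i, ])^2))
    flat <- (cc[, 1] + 1L) + dims[1] * cc[, 2] + dims[1] * dims[2] * cc[, 3]
    membrane[flat] <- pmax(membrane[flat],
                           exp(-((dd - radii[i] - off) / sigma_m)^2))
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D <- sqrt(sum((centres[i, ] - centres[j, ])^2))
      if (D >= radii[i] + radii[j]) next
      lo <- pmax(floor((pmin(centres[i, ], centres[j, ]) - max(radii)) / sp), 0)
      hi <- pmin(ceiling((pmax(centres[i, ], centres[j, ]) + max(radii)) / sp), dims - 1)
      cc <- box_coords(lo, hi)
      pos <- sweep(cc, 2, sp, `*`)
      di <- sqrt(colSums((t(pos) - centres[i, ])^2))
      dj <- sqrt(colSums((t(pos) - centres[j, ])^2))
      lens <- di <= radii[i] + sigma_m & dj <= radii[j] + sigma_m
      if (!any(lens)) next
      val <- exp(-((di - dj) / 2 / sigma_m)^2) * lens
      flat <- (cc[, 1] + 1L) + dims[1] * cc[, 2] + dims[1] * dims[2] * cc[, 3]
      membrane[flat] <- pmax(membrane[flat], val)
    }
  }

  edu <- NULL
  if (isTRUE(spec$edu)) {
    edu <- array(0, dim = dims)
    for (i in which(edu_pos)) {
      sel <- which(labels == i)
      edu[sel] <- 1
    }
  }

  degrade <- function(arr, is_edu = FALSE) {
    if (!is.null(spec$axial_gain)) {
      ax <- (seq_len(dims[1]) - 1) * sp[1]
      arr <- arr * array(spec$axial_gain(ax), dim = dims)
    }
    if (spec$z_attenuation > 0) {
      zf <- exp(-spec$z_attenuation * (seq_len(dims[3]) - 1) * sp[3])
      arr <- sweep(arr, 3, zf, `*`)
    }
    if (spec$psf_sigma_um > 0) arr <- gauss_blur3d(arr, spec$psf_sigma_um, sp)
    if (isTRUE(spec$poisson)) {
      scale <- 50
      arr <- array(rpois(length(arr), arr * scale) / scale, dim = dims)
    }
    if (spec$noise_sd > 0)
      arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), dim = dims)
    arr[arr < 0] <- 0
    arr
  }
  dna_out <- degrade(dna)
  memb_out <- degrade(membrane)
  edu_out <- if (!is.null(edu)) degrade(edu, TRUE) else NULL

  cells <- tibble::tibble(
    cell = seq_len(n),
    x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
    radius_um = radii, phase = phases, content = content, edu = edu_pos)

  list(dna = voxel_stack(dna_out, sp, "dna"),
       membrane = voxel_stack(memb_out, sp, "membrane"),
       edu = if (!is.null(edu_out)) voxel_stack(edu_out, sp, "edu") else NULL,
       truth = list(centers_um = centres, radii_um = radii,
                    labels = label_volume(labels, sp), cells = cells))
}

# voxels face-adjacent (6-connectivity) to a different nonzero label
.label_boundaries <- function(labels) {
  d <- dim(labels)
  out <- array(FALSE, dim = d)
  if (d[1] > 1) {
    a <- labels[-d[1], , , drop = FALSE]; b <- labels[-1, , , drop = FALSE]
    w <- a != b & a > 0L & b > 0L
    out[-d[1], , ] <- out[-d[1], , , drop = FALSE] | w
    out[-1, , ] <- out[-1, , , drop = FALSE] | w
  }
  if (d[2] > 1) {
    a <- labels[, -d[2], , drop = FALSE]; b <- labels[, -1, , drop = FALSE]
    w <- a != b & a > 0L & b > 0L
    out[, -d[2], ] <- out[, -d[2], , drop = FALSE] | w
    out[, -1, ] <- out[, -1, , drop = FALSE] | w
  }
  if (d[3] > 1) {
    a <- labels[, , -d[3], drop = FALSE]; b <- labels[, , -1, drop = FALSE]
    w <- a != b & a > 0L & b > 0L
    out[, , -d[3]] <- out[, , -d[3], drop = FALSE] | w
    out[, , -1] <- out[, , -1, drop = FALSE] | w
  }
  out
}

#' Jitter seed points by uniform noise in a ball
#'
#' Each centre is displaced by an independent uniform draw from the ball of
#' radius `rho_um` (rejection sampling from the bounding cube, exact). The
#' mean displacement magnitude converges to `3 * rho / 4`.
#'
#' @param centers matrix (n x 3) of micrometre coordinates.
#' @param rho_um jitter ball radius in micrometres.
#' @param seed RNG seed.
#' @return Displaced centre matrix.
#' @export
jitter_seeds <- function(centers, rho_um, seed = 1L) {
  stopifnot(rho_um >= 0)
  centers <- rbind(centers)
  if (rho_um == 0) return(centers)
  set.seed(sub_seed(seed, 2L))
  n <- nrow(centers)
  disp <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3, -1, 1)
      if (sum(u^2) <= 1) break
    }
    disp[i, ] <- u * rho_um
  }
  centers + disp
}

#' Artificially degrade a guide image
#'
#' Emulates suboptimal staining: a kernel is cropped from the guide,
#' inverted, clamped so no value exceeds 0.85, rescaled to `[0, 1]`, tiled to
#' the guide shape (starting at voxel (0,0,0), wrapping by repetition) and
#' multiplied elementwise into the guide.
#'
#' @param guide a `voxel_stack` with values in `[0, 1]`.
#' @param crop_origin 0-based voxel origin of the crop.
#' @param crop_size crop dimensions in voxels (default the 108 x 108 x 40
#'   section used for full-size stacks; pass a smaller size for phantoms).
#' @return Degraded `voxel_stack`.
#' @export
degrade_guide <- function(guide, crop_origin = c(0L, 0L, 0L),
                          crop_size = c(108L, 108L, 40L)) {
  stopifnot(inherits(guide, "voxel_stack"))
  d <- dim(guide$data)
  crop_origin <- as.integer(crop_origin)
  crop_size <- pmin(as.integer(crop_size), d - crop_origin)
  if (any(crop_size < 1L)) stop("crop does not fit inside the guide")
  K <- guide$data[crop_origin[1] + seq_len(crop_size[1]),
                  crop_origin[2] + seq_len(crop_size[2]),
                  crop_origin[3] + seq_len(crop_size[3]), drop = FALSE]
  K <- 1 - K                      # invert
  K[K > 0.85] <- 0.85             # clamp so no value exceeds 0.85
  rng <- range(K)
  if (rng[2] - rng[1] <= 0)
    stop("constant degradation kernel: rescale to [0,1] undefined")
  K <- (K - rng[1]) / (rng[2] - rng[1])
  tile_idx <- function(nd, nk) ((seq_len(nd) - 1L) %% nk) + 1L
  Kt <- K[tile_idx(d[1], crop_size[1]),
          tile_idx(d[2], crop_size[2]),
          tile_idx(d[3], crop_size[3]), drop = FALSE]
  voxel_stack(guide$data * Kt, guide$spacing, paste0(guide$channel, "_degraded"))
}
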