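# Guide-image construction. Two routes:
#  * membrane route (worm gonad / olfactory epithelium): sliding-window
#    sharpening, Gaussian blur, Hessian sheet enhancement, Gaussian blur;
#  * DNA route (pre-implantation embryo): adaptive threshold fitted to local
#    means around detections, median filter, inversion, blur.
# Guides are rescaled to [0, 1]; high values mark boundaries.

#' Sliding-window sharpening normalisation
#'
#' Divides each voxel by the mean over a 2-D sliding square parallel to the
#' xy-plane centred on it. Removes low-frequency gain (including z-dependent
#' attenuation) since a global multiplicative factor per plane cancels.
#' Local means below `eps_frac * max(image)` are clamped to that floor.
#'
#' @param stack a `voxel_stack`.
#' @param window_um side of the sliding square in micrometres (typically the
#'   average cell diameter).
#' @param eps_frac near-zero guard for the local mean.
#' @param mean_floor_frac additional floor on the local mean as a fraction
#'   of the global mean intensity; keeps the normalisation from amplifying
#'   noise in signal-free regions.
#' @return Normalised `voxel_stack`.
#' @export
sharpen_normalize <- function(stack, window_um, eps_frac = 1e-6,
                              mean_floor_frac = 0.5) {
  stopifnot(inherits(stack, "voxel_stack"), window_um > 0)
  d <- dim(stack$data)
  wx <- max(1L, 2L * floor(window_um / stack$spacing[1] / 2) + 1L)
  wy <- max(1L, 2L * floor(window_um / stack$spacing[2] / 2) + 1L)
  if (wx > d[1] || wy > d[2]) stop("window larger than the xy plane")
  box <- function(n) rep(1 / n, n)
  m <- cpp_conv1d(as.numeric(stack$data), d, box(wx), 0L)
  m <- cpp_conv1d(m, d, box(wy), 1L)
  eps <- max(eps_frac * max(stack$data),
             mean_floor_frac * mean(stack$data))
  m[m < eps] <- eps
  voxel_stack(array(as.numeric(stack$data) / m, dim = d), stack$spacing,
              paste0(stack$channel, "_sharp"))
}

# per-voxel eigenvalues of the 3x3 Hessian of a blurred image, ascending
# (d1 <= d2 <= d3), spacing-aware central differences, borders replicated
hessian_eigenvalues <- function(arr, spacing) {
  d <- dim(arr)
  sh <- function(ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  sx <- spacing[1]; sy <- spacing[2]; sz <- spacing[3]
  hxx <- (sh(1, 1) - 2 * arr + sh(1, -1)) / sx^2
  hyy <- (sh(2, 1) - 2 * arr + sh(2, -1)) / sy^2
  hzz <- (sh(3, 1) - 2 * arr + sh(3, -1)) / sz^2
  sh2 <- function(a1, b1, a2, b2) {
    idx <- lapply(d, seq_len)
    idx[[a1]] <- pmin(pmax(idx[[a1]] + b1, 1L), d[a1])
    idx[[a2]] <- pmin(pmax(idx[[a2]] + b2, 1L), d[a2])
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  hxy <- (sh2(1, 1, 2, 1) - sh2(1, 1, 2, -1) - sh2(1, -1, 2, 1) + sh2(1, -1, 2, -1)) / (4 * sx * sy)
  hxz <- (sh2(1, 1, 3, 1) - sh2(1, 1, 3, -1) - sh2(1, -1, 3, 1) + sh2(1, -1, 3, -1)) / (4 * sx * sz)
  hyz <- (sh2(2, 1, 3, 1) - sh2(2, 1, 3, -1) - sh2(2, -1, 3, 1) + sh2(2, -1, 3, -1)) / (4 * sy * sz)

  # closed-form eigenvalues of a symmetric 3x3 (trigonometric method)
  a <- as.numeric(hxx); b <- as.numeric(hyy); cq <- as.numeric(hzz)
  dd <- as.numeric(hxy); e <- as.numeric(hxz); f <- as.numeric(hyz)
  q <- (a + b + cq) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (cq - q)^2 + 2 * (dd^2 + e^2 + f^2)
  p <- sqrt(pmax(p2 / 6, 0))
  ok <- p > 1e-300
  A <- (a - q) / p; B <- (b - q) / p; Cq <- (cq - q) / p
  D <- dd / p; E <- e / p; Fq <- f / p
  detB <- A * (B * Cq - Fq^2) - D * (D * Cq - Fq * E) + E * (D * Fq - B * E)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)               # largest
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)  # smallest
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  list(d1 = array(e3, dim = d), d2 = array(e2, dim = d), d3 = array(e1, dim = d))
}

#' Hessian sheet enhancement
#'
#' Blurs the image with a Gaussian of sd `sigma_um`, computes the per-voxel
#' Hessian eigenvalues d1 <= d2 <= d3 (spacing-aware), and the sheetness
#' response `-d1 * exp(-(d2/(2 d1))^2) * exp(-(d3/(2 d1))^2)` wherever
#' d1 < 0 (bright sheet on dark background), 0 elsewhere.
#'
#' @param stack a `voxel_stack`.
#' @param sigma_um Gaussian sd in micrometres (typically the membrane
#'   thickness).
#' @return `voxel_stack` of sheetness responses.
#' @export
sheetness <- function(stack, sigma_um) {
  stopifnot(inherits(stack, "voxel_stack"))
  arr <- gauss_blur3d(stack$data, sigma_um, stack$spacing)
  ev <- hessian_eigenvalues(arr, stack$spacing)
  out <- sheetness_from_eigenvalues(ev$d1, ev$d2, ev$d3)
  voxel_stack(array(out, dim = dim(arr)), stack$spacing,
              paste0(stack$channel, "_sheet"))
}

#' @rdname sheetness
#' @param d1,d2,d3 ordered Hessian eigenvalues (d1 most negative).
#' @export
sheetness_from_eigenvalues <- function(d1, d2, d3) {
  out <- -d1 * exp(-(d2 / (2 * d1))^2) * exp(-(d3 / (2 * d1))^2)
  out[!(d1 < 0)] <- 0
  out[!is.finite(out)] <- 0
  out
}

#' Membrane-route guide image
#'
#' Four-step chain: sliding-window sharpening (window = average cell
#' diameter), Gaussian blur (sd = membrane thickness, folded into the sheet
#' enhancement), Hessian sheet enhancement, final Gaussian blur. The result
#' is rescaled to `[0, 1]`; boundaries are high.
#'
#' @param membrane membrane-channel `voxel_stack`.
#' @param cell_diameter_um average cell diameter (sharpening window).
#' @param membrane_um membrane thickness (blur sd).
#' @param saturate saturate boundary responses to 1 (Otsu-rescaled clip).
#' @return Guide `voxel_stack` in `[0, 1]`.
#' @export
make_guide_worm <- function(membrane, cell_diameter_um, membrane_um,
                            saturate = TRUE) {
  s <- sharpen_normalize(membrane, cell_diameter_um)
  s <- sheetness(s, membrane_um)          # blur + sheet enhancement
  arr <- gauss_blur3d(s$data, membrane_um, s$spacing)
  arr <- rescale01(arr)
  if (isTRUE(saturate)) {
    # boundary responses saturate the intensity range (walls ~ 1), as in a
    # well-stained guide: rescale by the Otsu split between background and
    # sheet responses and clip
    pos <- arr[arr > 1e-6 * max(arr)]
    if (length(pos) > 0) {
      thr <- otsu_threshold(pos)
      if (is.finite(thr) && thr > 0) arr <- pmin(arr / thr, 1)
    }
  }
  voxel_stack(arr, membrane$spacing, "guide")
}

#' DNA-route guide image (adaptive threshold model)
#'
#' Computes the mean DNA value in a small window around each detection, fits
#' the gain model `m(x,y,z) = exp(c1 z) (c2 x + c3 y + c4)` by least squares
#' (log-linearised start, nonlinear refinement), thresholds the stack at
#' `t = k * model`, median-filters the binary image, inverts it and blurs.
#'
#' @param dna DNA-channel `voxel_stack`.
#' @param detections detection table (micrometre coordinates).
#' @param k threshold scale (1/3 works well in practice).
#' @param window_um window for the local means (default half cell diameter).
#' @param median_radius median filter radius in voxels.
#' @param blur_um final blur sd.
#' @param cell_diameter_um average cell diameter.
#' @return Guide `voxel_stack` in `[0, 1]`.
#' @export
make_guide_embryo <- function(dna, detections, k = 1 / 3,
                              cell_diameter_um = 4,
                              window_um = cell_diameter_um / 2,
                              median_radius = 1L, blur_um = 0.5) {
  stopifnot(inherits(dna, "voxel_stack"), k > 0)
  cen <- as.matrix(detections[, c("x_um", "y_um", "z_um")])
  if (nrow(cen) < 4) stop("need at least 4 detections to fit the gain model")
  d <- dim(dna$data)
  sp <- dna$spacing
  half <- pmax(1L, round(window_um / 2 / sp))
  m_i <- apply(cen, 1, function(p) {
    v <- .um_to_vox_clamped(rbind(p), sp, d)[1, ]
    lo <- pmax(v - half, 0L); hi <- pmin(v + half, d - 1L)
    mean(dna$data[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L])
  })
  fit <- .fit_embryo_gain(cen, m_i)
  cf <- fit$coef
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  planar <- outer(cf[2] * xs, cf[3] * ys, `+`) + cf[4]
  thr <- array(0, dim = d)
  for (zi in seq_len(d[3])) thr[, , zi] <- k * exp(cf[1] * zs[zi]) * planar
  binary <- array(as.numeric(dna$data > thr), dim = d)
  binary <- median_filter3d(binary, median_radius)
  inv <- 1 - binary
  arr <- gauss_blur3d(inv, blur_um, sp)
  voxel_stack(rescale01(arr), sp, "guide")
}

# least-squares fit of m = exp(c1 z)(c2 x + c3 y + c4); nonlinear refinement
# seeded from a log-linearised estimate; degenerate fits fall back to the
# constant model with a warning
.fit_embryo_gain <- function(cen, m_i) {
  ok <- is.finite(m_i) & m_i > 0
  constant <- function() {
    warning("degenerate gain fit; falling back to constant model")
    list(coef = c(0, 0, 0, mean(m_i[ok])), fallback = TRUE)
  }
  if (sum(ok) < 4) return(constant())
  df <- data.frame(x = cen[ok, 1], y = cen[ok, 2], z = cen[ok, 3], m = m_i[ok])
  st <- tryCatch({
    lf <- lm(log(m) ~ z, data = df)
    c1_0 <- coef(lf)[["z"]]
    lin <- lm(I(m / exp(c1_0 * z)) ~ x + y, data = df)
    c(c1 = c1_0, c2 = coef(lin)[["x"]], c3 = coef(lin)[["y"]],
      c4 = coef(lin)[["(Intercept)"]])
  }, error = function(e) NULL)
  if (is.null(st)) return(constant())
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ exp(c1 * z) * (c2 * x + c3 * y + c4), data = df,
                      start = as.list(st),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (all(is.finite(st))) return(list(coef = unname(st), fallback = FALSE))
    return(constant())
  }
  list(coef = unname(coef(fit)), fallback = FALSE)
}
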