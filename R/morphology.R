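# Nuclear-morphology phase classification: mid-cell 2D crops (<= 34x34),
# Otsu-threshold features (spot count, foreground area), center-surround
# Haar-like features via integral images, and one-vs-rest linear SVMs with
# per-phase hyperparameters.

#' Crop a 2-D cell patch at the cell's mid-z slice
#'
#' Takes the z-slice at the median z of the mask, crops the in-plane
#' bounding box of the mask (clipped to at most `max_size` pixels per side,
#' centred on the mask centroid), and zeroes pixels outside the mask.
#'
#' @param stack DNA `voxel_stack`.
#' @param labels a `label_volume`.
#' @param cell_id cell index.
#' @param max_size maximum patch side (pixels).
#' @return List of class `cell_patch`: `intensity` and `mask` matrices
#'   (<= max_size squared), plus the slice index.
#' @export
crop_cell_patch <- function(stack, labels, cell_id, max_size = 34L) {
  L <- labels$labels
  w <- which(L == cell_id, arr.ind = TRUE)
  if (nrow(w) == 0) stop("cell id ", cell_id, " not present in labels")
  zmid <- round(median(w[, 3]))
  sl <- L[, , zmid] == cell_id
  if (!any(sl)) { # median z can fall on a plane the mask skips; take nearest
    zs <- sort(unique(w[, 3]))
    zmid <- zs[which.min(abs(zs - zmid))]
    sl <- L[, , zmid] == cell_id
  }
  ij <- which(sl, arr.ind = TRUE)
  cen <- round(colMeans(ij))
  half <- max_size %/% 2L
  xr <- max(min(ij[, 1]), cen[1] - half + 1L):min(max(ij[, 1]), cen[1] + half)
  yr <- max(min(ij[, 2]), cen[2] - half + 1L):min(max(ij[, 2]), cen[2] + half)
  xr <- xr[xr >= 1 & xr <= nrow(sl)]
  yr <- yr[yr >= 1 & yr <= ncol(sl)]
  intens <- stack$data[xr, yr, zmid, drop = TRUE] * sl[xr, yr]
  structure(list(intensity = matrix(intens, length(xr), length(yr)),
                 mask = sl[xr, yr, drop = FALSE], z = zmid, cell = cell_id),
            class = "cell_patch")
}

#' Otsu threshold of a vector of intensities
#'
#' Exhaustive search over 256 histogram levels for the threshold maximising
#' the between-class variance.
#'
#' @param v numeric intensities.
#' @param levels histogram resolution.
#' @return The threshold value.
#' @export
otsu_threshold <- function(v, levels = 256L) {
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- as.numeric(tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                                levels), nbins = levels))
  mids <- (edges[-1] + edges[-(levels + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  m0 <- cumsum(h * mids) / pmax(w0, 1)
  m1 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w1, 1)
  between <- w0 * w1 * (m0 - m1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(between)
  edges[k + 1L] # class boundary just above bin k
}

# 8-connected component count of a logical matrix (iterative flood fill)
.count_components <- function(mask) {
  if (!any(mask)) return(0L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[s] > 0L) next
      lab[s] <- cur
      i <- ((s - 1L) %% nr) + 1L
      j <- ((s - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          t <- ii + nr * (jj - 1L)
          if (mask[t] && lab[t] == 0L) stack <- c(stack, t)
        }
      }
    }
  }
  cur
}

#' Otsu features of a cell patch
#'
#' Thresholds the in-mask DNA intensities with Otsu's method and reports the
#' number of connected components of the foreground (the number of spots,
#' 8-connectivity) and the foreground pixel count (the spatial extent).
#' Constant patches give `(0, 0)` with a warning.
#'
#' @param patch a `cell_patch`.
#' @return Named numeric: `n_components`, `area`.
#' @export
otsu_features <- function(patch) {
  v <- patch$intensity[patch$mask]
  if (length(v) == 0 || diff(range(v)) <= 0) {
    warning("constant patch: Otsu threshold undefined")
    return(c(n_components = 0, area = 0))
  }
  thr <- otsu_threshold(v)
  fg <- patch$intensity >= thr & patch$mask
  c(n_components = .count_components(fg), area = sum(fg))
}

#' Enumerate center-surround Haar-like features
#'
#' A feature is an outer square r1 (side `s1`) with an inner square r2 of
#' side `s1 - 2` exactly centred in it (a one-pixel surround ring), placed
#' at every position where r1 fits inside the `frame x frame` image. With
#' `frame = 34` and outer sides up to 8 pixels wide this enumerates exactly
#' 5239 features.
#'
#' @param frame image frame side (pixels).
#' @param max_outer maximum outer square side.
#' @return Tibble: `x0`, `y0` (0-based outer corner), `s1`, `s2`.
#' @export
enumerate_haar <- function(frame = 34L, max_outer = 8L) {
  stopifnot(frame >= max_outer)
  if (max_outer < 3L)
    return(tibble::tibble(x0 = integer(0), y0 = integer(0),
                          s1 = integer(0), s2 = integer(0)))
  out <- lapply(3:max_outer, function(s1) {
    npos <- frame - s1 + 1L
    g <- expand.grid(x0 = 0:(npos - 1L), y0 = 0:(npos - 1L))
    tibble::tibble(x0 = g$x0, y0 = g$y0, s1 = s1, s2 = s1 - 2L)
  })
  do.call(rbind, out)
}

# summed-area table with a zero top/left border row
.integral_image <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(apply(m, 2, cumsum), nr, nc)
  cs <- matrix(t(apply(cs, 1, cumsum)), nr, nc)
  out <- matrix(0, nr + 1L, nc + 1L)
  out[-1, -1] <- cs
  out
}

# rectangle sum via the integral image: 0-based corner (x0, y0), size s
.rect_sum <- function(ii, x0, y0, s) {
  ii[cbind(x0 + s + 1L, y0 + s + 1L)] - ii[cbind(x0 + 1L, y0 + s + 1L)] -
    ii[cbind(x0 + s + 1L, y0 + 1L)] + ii[cbind(x0 + 1L, y0 + 1L)]
}

#' Haar-like feature responses of a patch
#'
#' Response = mean pixel value within the inner square minus the mean within
#' the surround (outer square minus inner square). The patch is embedded
#' centred in a `frame x frame` zero background; responses are computed for
#' all features at once via an integral image.
#'
#' @param patch a `cell_patch` (or numeric matrix).
#' @param features feature table from [enumerate_haar()].
#' @param frame embedding frame side.
#' @return Numeric vector of responses (one per feature).
#' @export
haar_responses <- function(patch, features = enumerate_haar(), frame = 34L) {
  m <- if (inherits(patch, "cell_patch")) patch$intensity else patch
  emb <- matrix(0, frame, frame)
  ox <- (frame - nrow(m)) %/% 2L
  oy <- (frame - ncol(m)) %/% 2L
  emb[ox + seq_len(nrow(m)), oy + seq_len(ncol(m))] <- m
  ii <- .integral_image(emb)
  s1 <- features$s1; s2 <- features$s2
  outer_sum <- .rect_sum(ii, features$x0, features$y0, s1)
  inner_sum <- .rect_sum(ii, features$x0 + (s1 - s2) %/% 2L,
                         features$y0 + (s1 - s2) %/% 2L, s2)
  inner_sum / s2^2 - (outer_sum - inner_sum) / (s1^2 - s2^2)
}

#' Morphology feature matrix for a set of cells
#'
#' Rows = cells; columns = Otsu spot count, Otsu foreground area, and all
#' Haar-like responses.
#'
#' @param stack DNA `voxel_stack`.
#' @param labels a `label_volume`.
#' @param ids cell ids (default all).
#' @param features Haar feature table.
#' @param intensity_scale intensities are rescaled so the stack maximum maps
#'   to this value (default 4095, a 12-bit acquisition range) so that
#'   feature magnitudes, and hence the per-phase SVM box constraints, live
#'   on the scale of typical confocal data.
#' @return Numeric matrix with rownames = cell ids.
#' @export
morphology_features <- function(stack, labels, ids = NULL,
                                features = enumerate_haar(),
                                intensity_scale = 4095) {
  L <- labels$labels
  if (!is.null(intensity_scale) && max(stack$data) > 0)
    stack <- voxel_stack(stack$data / max(stack$data) * intensity_scale,
                         stack$spacing, stack$channel)
  if (is.null(ids)) ids <- sort(setdiff(unique(as.integer(L)), 0L))
  rows <- lapply(ids, function(k) {
    p <- crop_cell_patch(stack, labels, k)
    of <- suppressWarnings(otsu_features(p))
    c(of, haar_responses(p, features))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  colnames(X) <- c("n_components", "area",
                   paste0("haar", seq_len(nrow(features))))
  X
}

#' Train one-vs-rest phase classifiers
#'
#' One linear SVM per phase with per-phase hyperparameters (box constraint
#' and tolerance); box constraints are scaled per class as `N / (2 N_k)`.
#' Features are used on their natural (acquisition-range) scale, which the
#' per-phase box constraints assume. Performance is estimated over repeated
#' random equally-sized, non-intersecting train/test splits.
#'
#' @param X feature matrix (cells x features).
#' @param phases character phase label per row (G1/S/G2/M).
#' @param cost named per-phase box constraints.
#' @param tolerance named per-phase tolerances.
#' @param repeats number of random 50/50 splits.
#' @param seed RNG seed.
#' @return Object of class `phase_classifiers`: per-phase mean sensitivity /
#'   specificity with spread, and the per-repeat table.
#' @export
train_phase_classifiers <- function(X, phases,
                                    cost = c(G1 = 1e-5, S = 1e-3,
                                             G2 = 1e-2, M = 1e-3),
                                    tolerance = c(G1 = 1e-7, S = 1e-8,
                                                  G2 = 1e-8, M = 1e-8),
                                    repeats = 25L, seed = 1L) {
  stopifnot(nrow(X) == length(phases), nrow(X) >= 20)
  phases <- as.character(phases)
  present <- intersect(names(cost), unique(phases))
  if (length(unique(phases)) < 2) stop("need at least 2 phases present")
  for (ph in setdiff(names(cost), present))
    warning("phase ", ph, " absent; classifier skipped")
  set.seed(sub_seed(seed, 4L))
  n <- nrow(X)
  res <- list()
  for (r in seq_len(repeats)) {
    tr <- sample(n, n %/% 2L)
    te <- setdiff(seq_len(n), tr)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    for (ph in present) {
      ytr <- factor(ifelse(phases[tr] == ph, "pos", "neg"),
                    levels = c("neg", "pos"))
      yte <- phases[te] == ph
      if (length(unique(ytr)) < 2 || !any(yte) || all(yte)) next
      wts <- length(ytr) / (2 * table(ytr))
      m <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost[[ph]],
                      tolerance = tolerance[[ph]], scale = FALSE,
                      class.weights = wts)
      pred <- predict(m, Xte) == "pos"
      res[[length(res) + 1L]] <- tibble::tibble(
        repeat_id = r, phase = ph,
        sensitivity = sum(pred & yte) / sum(yte),
        specificity = sum(!pred & !yte) / sum(!yte))
    }
  }
  tab <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(tab, tab$phase), function(dd)
    tibble::tibble(phase = dd$phase[1],
                   sensitivity = mean(dd$sensitivity),
                   specificity = mean(dd$specificity),
                   sens_sd = sd(dd$sensitivity), spec_sd = sd(dd$specificity),
                   n_repeats = nrow(dd))))
  structure(list(summary = summ, repeats = tab,
                 cost = cost, tolerance = tolerance),
            class = "phase_classifiers")
}

#' @export
print.phase_classifiers <- function(x, ...) {
  cat("<phase_classifiers>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Tidy phase-classifier statistics
#'
#' @param x a `phase_classifiers` object.
#' @param ... unused.
#' @return Tibble of per-phase mean sensitivity and specificity.
#' @export
tidy.phase_classifiers <- function(x, ...) x$summary

#' Glance at phase-classifier statistics
#'
#' @param x a `phase_classifiers` object.
#' @param ... unused.
#' @return One-row tibble with the worst-phase sensitivity and specificity.
#' @export
glance.phase_classifiers <- function(x, ...) {
  tibble::tibble(min_sensitivity = min(x$summary$sensitivity),
                 min_specificity = min(x$summary$specificity),
                 n_phases = nrow(x$summary))
}
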