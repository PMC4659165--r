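# Per-cell spatial position and fluorescence quantification: top-layeredness,
# geodesic and cell-row positions, DNA-content normalisation (worm-gonad and
# olfactory-epithelium recipes), EdU quantification/classification, and
# cell-cycle phase indices.

#' Top-layeredness
#'
#' Fraction of a cell's z-projection footprint that is unobscured: for each
#' xy column, the first nonzero label encountered along z "sees" the
#' objective; theta of a cell is the fraction of its footprint columns where
#' it is that first label. theta = 1 means direct line of sight, theta = 0
#' completely obscured; `theta > 0.1` is a good top-layer cut.
#'
#' @param labels a `label_volume`.
#' @param direction `"up"` if the objective is at z = 0 (first nonzero label
#'   along increasing z is visible), `"down"` for the opposite convention.
#' @return Tibble: `cell`, `theta`, footprint column count.
#' @export
top_layeredness <- function(labels, direction = c("up", "down")) {
  direction <- match.arg(direction)
  L <- labels$labels
  d <- dim(L)
  zs <- if (direction == "up") seq_len(d[3]) else rev(seq_len(d[3]))
  first <- matrix(0L, d[1], d[2])
  for (z in rev(zs)) { # iterate far-to-near so the nearest plane wins
    pl <- L[, , z]
    first[pl > 0L] <- pl[pl > 0L]
  }
  ids <- sort(setdiff(unique(as.integer(L)), 0L))
  out <- lapply(ids, function(k) {
    fp <- apply(L == k, c(1, 2), any)
    n_fp <- sum(fp)
    vis <- sum(first[fp] == k)
    tibble::tibble(cell = k, theta = if (n_fp > 0) vis / n_fp else NA_real_,
                   footprint = n_fp)
  })
  do.call(rbind, out)
}

#' Geodesic position along a fitted axis curve
#'
#' Fits a simplified principal curve (centres ordered along their first
#' principal component, smoothed by a running mean, joined as a polyline),
#' projects each centre onto the curve and reports the arc length from the
#' distal end to the projection.
#'
#' @param centers matrix (n x 3) of cell centres (micrometres).
#' @param distal_point micrometre coordinates of the distal end.
#' @param smooth_window running-mean half-width (in ordered points).
#' @return Tibble: `cell`, `geodesic_um`; attribute `curve` holds the
#'   polyline.
#' @export
geodesic_positions <- function(centers, distal_point, smooth_window = 3L) {
  centers <- rbind(centers)
  n <- nrow(centers)
  if (n < 3) stop("need at least 3 cells to fit an axis curve")
  if (all(apply(centers, 2, sd) < 1e-12)) stop("degenerate centre cloud")
  pc <- prcomp(centers, center = TRUE, scale. = FALSE)
  t1 <- pc$x[, 1]
  ord <- order(t1)
  pts <- centers[ord, , drop = FALSE]
  # running mean with shrinking window at the ends (keeps endpoints anchored)
  sm <- pts
  for (i in seq_len(n)) {
    h <- min(smooth_window, i - 1, n - i)
    sm[i, ] <- colMeans(pts[(i - h):(i + h), , drop = FALSE])
  }
  # orient the polyline so the end nearest the distal point comes first
  if (sum((sm[n, ] - distal_point)^2) < sum((sm[1, ] - distal_point)^2))
    sm <- sm[n:1, , drop = FALSE]
  seglen <- sqrt(rowSums(diff(sm)^2))
  cum <- c(0, cumsum(seglen))
  # project every centre on the polyline
  proj_arc <- vapply(seq_len(n), function(i) {
    p <- centers[i, ]
    best <- Inf; arc <- 0
    for (s in seq_len(nrow(sm) - 1)) {
      a <- sm[s, ]; b <- sm[s + 1, ]
      ab <- b - a
      L2 <- sum(ab^2)
      tt <- if (L2 > 0) min(1, max(0, sum((p - a) * ab) / L2)) else 0
      q <- a + tt * ab
      d2 <- sum((p - q)^2)
      if (d2 < best) { best <- d2; arc <- cum[s] + tt * sqrt(L2) }
    }
    arc
  }, numeric(1))
  out <- tibble::tibble(cell = seq_len(n), geodesic_um = proj_arc)
  attr(out, "curve") <- sm
  out
}

#' Cell rows from the touching-masks graph
#'
#' Builds the adjacency graph of cells whose masks share a face-adjacent
#' voxel pair (6-connectivity) and assigns row = 1 + unweighted shortest-path
#' length from the distal cell. Unreachable cells get `NA` rows.
#'
#' @param labels a `label_volume`.
#' @param distal_cell id of the distal-most cell.
#' @return Tibble: `cell`, `row`.
#' @export
cell_rows <- function(labels, distal_cell) {
  L <- labels$labels
  ids <- sort(setdiff(unique(as.integer(L)), 0L))
  if (!(distal_cell %in% ids)) stop("distal cell id not present in labels")
  g <- .touching_graph(labels)
  dist <- igraph::distances(g, v = match(distal_cell, ids))[1, ]
  row <- ifelse(is.finite(dist), dist + 1, NA_real_)
  tibble::tibble(cell = ids, row = as.numeric(row))
}

# touching-masks adjacency graph (nodes in id-sorted order)
.touching_graph <- function(labels) {
  L <- labels$labels
  ids <- sort(setdiff(unique(as.integer(L)), 0L))
  d <- dim(L)
  pair_up <- function(a, b) {
    sel <- a != b & a > 0L & b > 0L
    cbind(a[sel], b[sel])
  }
  prs <- rbind(
    if (d[1] > 1) pair_up(L[-d[1], , , drop = FALSE], L[-1, , , drop = FALSE]),
    if (d[2] > 1) pair_up(L[, -d[2], , drop = FALSE], L[, -1, , drop = FALSE]),
    if (d[3] > 1) pair_up(L[, , -d[3], drop = FALSE], L[, , -1, drop = FALSE]))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (!is.null(prs) && nrow(prs) > 0) {
    e <- unique(t(apply(prs, 1, sort)))
    idx <- cbind(match(e[, 1], ids), match(e[, 2], ids))
    g <- igraph::add_edges(g, as.vector(t(idx)))
  }
  g
}

.touching_components <- function(labels) {
  igraph::components(.touching_graph(labels))$membership
}

# per-cell raw content (sum) and a pixel-value percentile inside each mask
.mask_sums <- function(arr, L, ids, pct = NULL) {
  sums <- numeric(length(ids))
  pcts <- numeric(length(ids))
  for (i in seq_along(ids)) {
    v <- arr[L == ids[i]]
    sums[i] <- sum(v)
    pcts[i] <- if (!is.null(pct)) quantile(v, pct, names = FALSE) else NA_real_
  }
  list(sum = sums, pct = pcts)
}

#' Worm-gonad DNA content normalisation
#'
#' Top-layer cells (`theta > theta_min`) are kept; raw contents are divided
#' by a smoothing spline (generalised cross-validation) of the per-cell 95th
#' percentile pixel value against geodesic distance; then, per spatial bin
#' of `bin_rows` cell rows, an affine map sends the bin's 10th percentile of
#' spline-normalised content to 2C and its 85th percentile to 4C. Bins with
#' fewer than `min_bin` cells are merged with their neighbour.
#'
#' @param records per-cell tibble with columns `cell`, `raw_dna`, `dna_p95`,
#'   `geodesic_um`, `row`, `theta`.
#' @param bin_rows bin size in cell rows.
#' @param theta_min top-layer cut.
#' @param min_bin minimum cells per bin before merging.
#' @return `records` filtered to the top layer with extra columns
#'   `spline_norm` and `c_value`.
#' @export
normalize_dna_worm <- function(records, bin_rows = 4L, theta_min = 0.1,
                               min_bin = 5L) {
  need <- c("raw_dna", "dna_p95", "geodesic_um", "row", "theta")
  stopifnot(all(need %in% names(records)))
  rec <- records[records$theta > theta_min & is.finite(records$row), ,
                 drop = FALSE]
  if (nrow(rec) < 4) stop("too few top-layer cells")
  ux <- length(unique(rec$geodesic_um))
  # staining gain acts multiplicatively, so the spline is fitted to the log
  # of the 95th-percentile values; the generalised cross-validation choice
  # of smoothness is capped at 5 degrees of freedom so per-cell content
  # fluctuations are not absorbed into the gain estimate
  lp <- log(pmax(rec$dna_p95, 1e-12))
  gain <- if (ux >= 4) {
    ss <- smooth.spline(rec$geodesic_um, lp, cv = FALSE)
    if (ss$df > 5) ss <- smooth.spline(rec$geodesic_um, lp, df = 5)
    exp(predict(ss, rec$geodesic_um)$y)
  } else {
    lf <- lm(lp ~ geodesic_um, data = cbind(rec, lp = lp))
    exp(predict(lf, cbind(rec, lp = lp)))
  }
  rec$spline_norm <- rec$raw_dna / pmax(gain, 1e-12)
  bin <- floor((rec$row - 1) / bin_rows)
  # merge small bins into the previous (or next) one
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_bin]
    if (length(small) == 0 || length(tab) == 1) break
    b <- as.numeric(small[1])
    others <- as.numeric(names(tab))[as.numeric(names(tab)) != b]
    nearest <- others[which.min(abs(others - b))]
    warning("merging under-populated spatial bin ", b, " into ", nearest)
    bin[bin == b] <- nearest
  }
  rec$c_value <- NA_real_
  for (b in unique(bin)) {
    sel <- bin == b
    q <- quantile(rec$spline_norm[sel], c(0.10, 0.85), names = FALSE)
    if (q[2] - q[1] <= 0) {
      rec$c_value[sel] <- 3
      next
    }
    rec$c_value[sel] <- 2 + (rec$spline_norm[sel] - q[1]) / (q[2] - q[1]) * 2
  }
  rec$dna_bin <- bin
  rec
}

#' Olfactory-epithelium DNA content normalisation
#'
#' Corrects the DNA stack for gain along x (second-order polynomial fitted
#' to the 90th percentile pixel intensity of each x-slice) and attenuation
#' along z (first-order polynomial fitted on the middle 25 z-slices), sums
#' corrected intensity per mask, and scales contents so that the median
#' M-phase cell has a C-value of exactly 4.
#'
#' @param stack DNA `voxel_stack`.
#' @param labels a `label_volume`.
#' @param mphase_ids cell ids annotated as M-phase (at least one required).
#' @return Tibble: `cell`, `content`, `c_value`.
#' @export
normalize_dna_oe <- function(stack, labels, mphase_ids) {
  if (length(mphase_ids) == 0)
    stop("no M-phase cells: DNA normalisation requires at least one")
  arr <- stack$data
  d <- dim(arr)
  # the 90th-percentile slice statistic is taken over tissue voxels (above
  # 1 % of the stack maximum); slices with too little tissue do not
  # constrain the gain fit (the fitted polynomial interpolates across them)
  floor_v <- 0.01 * max(arr)
  p90 <- function(v) {
    w <- v[v > floor_v]
    if (length(w) < 30) return(NA_real_)
    quantile(w, 0.9, names = FALSE)
  }
  p90_x <- vapply(seq_len(d[1]), function(i) p90(arr[i, , ]), numeric(1))
  xs <- seq_len(d[1])
  ok_x <- is.finite(p90_x)
  if (sum(ok_x) < 4) stop("too little tissue for the x-gain fit")
  fx <- lm(p90_x[ok_x] ~ poly(xs[ok_x], 2, raw = TRUE))
  gx <- pmax(cbind(1, xs, xs^2) %*% coef(fx), 1e-12)
  arr <- sweep(arr, 1, gx / mean(gx), `/`)
  nmid <- min(25L, d[3])
  zmid <- seq.int(floor((d[3] - nmid) / 2) + 1L, length.out = nmid)
  p90_z <- vapply(zmid, function(k) p90(arr[, , k]), numeric(1))
  ok_z <- is.finite(p90_z)
  gz <- if (sum(ok_z) >= 2) {
    fz <- lm(p90_z[ok_z] ~ zmid[ok_z])
    pmax(coef(fz)[1] + coef(fz)[2] * seq_len(d[3]), 1e-12)
  } else rep(1, d[3])
  arr <- sweep(arr, 3, gz / mean(gz), `/`)
  L <- labels$labels
  ids <- sort(setdiff(unique(as.integer(L)), 0L))
  ms <- .mask_sums(arr, L, ids)
  content <- ms$sum
  m_med <- median(content[ids %in% mphase_ids])
  if (!is.finite(m_med) || m_med <= 0) stop("M-phase reference content is degenerate")
  tibble::tibble(cell = ids, content = content, c_value = content / m_med * 4)
}

#' EdU content quantification and classification
#'
#' Median filter, clamp to `[t1, t2]`, rescale to `[0, 1]`, sum per mask,
#' affine-map the 10th and 85th percentiles of cellular contents to 0 and 1,
#' and threshold to EdU +/- status.
#'
#' @param stack EdU `voxel_stack`.
#' @param labels a `label_volume`.
#' @param t1,t2 clamp bounds (`t1 < t2`).
#' @param pos_threshold EdU-positive cut on the normalised content (set
#'   between the negative mode near 0 and the positive mode, as one would
#'   place a manual threshold on the content histogram).
#' @param median_radius median filter radius in voxels (0 disables).
#' @return Tibble: `cell`, `edu_content`, `edu_pos`.
#' @export
quantify_edu <- function(stack, labels, t1, t2, pos_threshold = 0.15,
                         median_radius = 1L) {
  if (t1 >= t2) stop("t1 must be < t2")
  arr <- stack$data
  if (median_radius > 0) arr <- median_filter3d(arr, median_radius)
  arr <- pmin(pmax(arr, t1), t2)
  arr <- (arr - t1) / (t2 - t1)
  L <- labels$labels
  ids <- sort(setdiff(unique(as.integer(L)), 0L))
  sums <- .mask_sums(arr, L, ids)$sum
  q <- quantile(sums, c(0.10, 0.85), names = FALSE)
  if (q[2] - q[1] <= 0) {
    warning("degenerate EdU content distribution; all statuses negative")
    return(tibble::tibble(cell = ids, edu_content = rep(0, length(ids)),
                          edu_pos = rep(FALSE, length(ids))))
  }
  contents <- (sums - q[1]) / (q[2] - q[1])
  tibble::tibble(cell = ids, edu_content = contents,
                 edu_pos = contents > pos_threshold)
}

#' Cell-cycle phase calls and phase indices per spatial bin
#'
#' EdU-positive cells are S-phase; EdU-negative cells with C-value below
#' `dna_split` are G1; EdU-negative cells with high C-value are G2/M.
#' Manual M annotations override to M. Indices are per-bin proportions.
#'
#' @param records tibble with `edu_pos`, `c_value` and a bin column.
#' @param bins name of the bin column (e.g. `"row"`).
#' @param dna_split C-value split between G1 and G2/M (default 3).
#' @param mphase_ids optional manually annotated M-phase cell ids.
#' @return List: `records` with a `phase` column, `indices` tibble of per-bin
#'   proportions, and `chisq` helper (function of two bin values).
#' @export
phase_indices <- function(records, bins = "row", dna_split = 3,
                          mphase_ids = integer(0)) {
  stopifnot(all(c("edu_pos", "c_value") %in% names(records)))
  phase <- ifelse(records$edu_pos, "S",
                  ifelse(records$c_value < dna_split, "G1", "G2M"))
  phase[records$cell %in% mphase_ids] <- "M"
  records$phase <- phase
  b <- records[[bins]]
  idx <- do.call(rbind, lapply(sort(unique(b[is.finite(b)])), function(bb) {
    sel <- b == bb & !is.na(b)
    n <- sum(sel)
    tibble::tibble(bin = bb, n = n,
                   G1 = mean(phase[sel] == "G1"),
                   S = mean(phase[sel] == "S"),
                   G2M = mean(phase[sel] == "G2M"),
                   M = mean(phase[sel] == "M"))
  }))
  chisq <- function(bin_a, bin_b) {
    ta <- table(factor(phase[b == bin_a], levels = c("G1", "S", "G2M", "M")))
    tb <- table(factor(phase[b == bin_b], levels = c("G1", "S", "G2M", "M")))
    keep <- (ta + tb) > 0
    chisq.test(rbind(ta[keep], tb[keep]))
  }
  list(records = records, indices = idx, chisq = chisq)
}

#' Assemble per-cell records from stacks and labels
#'
#' Convenience wrapper producing one row per cell with centre, raw DNA
#' content and 95th percentile, top-layeredness, geodesic position and cell
#' row — ready for [normalize_dna_worm()], [quantify_edu()] and
#' [phase_indices()].
#'
#' @param dna DNA `voxel_stack`.
#' @param labels a `label_volume`.
#' @param distal_point distal end (micrometres); defaults to the centre of
#'   the cell with the smallest x.
#' @return Tibble of per-cell records.
#' @export
cell_records <- function(dna, labels, distal_point = NULL) {
  L <- labels$labels
  ids <- sort(setdiff(unique(as.integer(L)), 0L))
  sp <- labels$spacing
  cen <- t(vapply(ids, function(k) {
    w <- which(L == k, arr.ind = TRUE) - 1L
    colMeans(w) * sp
  }, numeric(3)))
  ms <- .mask_sums(dna$data, L, ids, pct = 0.95)
  th <- top_layeredness(labels)
  if (is.null(distal_point)) distal_point <- cen[which.min(cen[, 1]), ]
  geo <- geodesic_positions(cen, distal_point)
  # the distal reference cell must sit in the main connected component of
  # the touching graph, else rows are undefined for most of the tissue
  comp <- .touching_components(labels)
  main <- which(comp == which.max(tabulate(comp)))
  distal_cell <- ids[main[which.min(geo$geodesic_um[main])]]
  rows <- cell_rows(labels, distal_cell)
  tibble::tibble(cell = ids,
                 x_um = cen[, 1], y_um = cen[, 2], z_um = cen[, 3],
                 raw_dna = ms$sum, dna_p95 = ms$pct,
                 theta = th$theta[match(ids, th$cell)],
                 geodesic_um = geo$geodesic_um,
                 row = rows$row[match(ids, rows$cell)])
}
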