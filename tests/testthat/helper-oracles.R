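# Independent brute-force reference implementations used to cross-check the
# package's optimised code paths. These are deliberately written as plain
# loops, straight from the definitions.

# mirror of C++ lround (round half away from zero)
oracle_lround <- function(x) trunc(x + 0.5 * sign(x))

# detection-window features: plain-loop HOG over xy and xz patches
oracle_window_features <- function(arr, center_vox, win, grid, nbins, scale = 1) {
  d <- dim(arr)
  patch <- function(xzplane) {
    P <- matrix(0, win, win)
    h <- win %/% 2
    for (v in 0:(win - 1)) for (u in 0:(win - 1)) {
      du <- oracle_lround(scale * (u - h))
      dv <- oracle_lround(scale * (v - h))
      x <- center_vox[1] + du
      if (xzplane) { y <- center_vox[2]; z <- center_vox[3] + dv }
      else { y <- center_vox[2] + dv; z <- center_vox[3] }
      if (x >= 0 && x < d[1] && y >= 0 && y < d[2] && z >= 0 && z < d[3])
        P[u + 1, v + 1] <- arr[x + 1, y + 1, z + 1]
    }
    P
  }
  hog <- function(P) {
    cellpx <- win %/% grid
    hist <- array(0, c(nbins, grid, grid))
    for (v in 0:(win - 1)) for (u in 0:(win - 1)) {
      um <- max(u - 1, 0); up <- min(u + 1, win - 1)
      vm <- max(v - 1, 0); vp <- min(v + 1, win - 1)
      du <- 0.5 * (P[up + 1, v + 1] - P[um + 1, v + 1])
      dv <- 0.5 * (P[u + 1, vp + 1] - P[u + 1, vm + 1])
      mag <- sqrt(du^2 + dv^2)
      if (mag <= 0) next
      th <- atan2(dv, du)
      if (th < 0) th <- th + pi
      if (th >= pi) th <- th - pi
      bin <- min(floor(th / pi * nbins), nbins - 1)
      gu <- min(u %/% cellpx, grid - 1)
      gv <- min(v %/% cellpx, grid - 1)
      hist[bin + 1, gu + 1, gv + 1] <- hist[bin + 1, gu + 1, gv + 1] + mag
    }
    out <- numeric(0)
    for (gv in 0:(grid - 1)) for (gu in 0:(grid - 1)) {
      h <- hist[, gu + 1, gv + 1]
      nrm <- sqrt(sum(h^2))
      out <- c(out, h / if (nrm > 0) nrm else 1, nrm)
    }
    out
  }
  Pxy <- patch(FALSE)
  Pxz <- patch(TRUE)
  c(mean(Pxy), hog(Pxy), hog(Pxz))
}

# exhaustive Otsu: try every histogram boundary, maximise between-class var
oracle_otsu <- function(v, levels = 256L) {
  edges <- seq(min(v), max(v), length.out = levels + 1L)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), levels)
  best <- -Inf; thr <- NA_real_
  for (k in 1:(levels - 1)) {
    lo <- v[bin <= k]; hi <- v[bin > k]
    if (length(lo) == 0 || length(hi) == 0) next
    bc <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; thr <- edges[k + 1] }
  }
  thr
}

# double-loop Haar response
oracle_haar <- function(patch_mat, x0, y0, s1, s2, frame = 34L) {
  emb <- matrix(0, frame, frame)
  ox <- (frame - nrow(patch_mat)) %/% 2L
  oy <- (frame - ncol(patch_mat)) %/% 2L
  emb[ox + seq_len(nrow(patch_mat)), oy + seq_len(ncol(patch_mat))] <- patch_mat
  o <- (s1 - s2) %/% 2L
  inner <- 0; outer <- 0
  for (xx in 1:s1) for (yy in 1:s1) {
    val <- emb[x0 + xx, y0 + yy]
    outer <- outer + val
    if (xx > o && xx <= o + s2 && yy > o && yy <= o + s2)
      inner <- inner + val
  }
  inner / s2^2 - (outer - inner) / (s1^2 - s2^2)
}

# O(n^2) greedy suppression
oracle_nonmax <- function(df, radius) {
  ord <- order(-df$score, seq_len(nrow(df)))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      dd <- sqrt((df$x_um[i] - df$x_um[k])^2 + (df$y_um[i] - df$y_um[k])^2 +
                 (df$z_um[i] - df$z_um[k])^2)
      if (dd <= radius) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# exhaustive detection matching straight from the stated rule
oracle_match <- function(pts, truth, radius) {
  nd <- nrow(pts); nt <- nrow(truth)
  tp <- rep(FALSE, nd); fn <- 0L
  for (t in seq_len(nt)) {
    dd <- sqrt(rowSums(sweep(pts, 2, truth[t, ])^2))
    inr <- which(dd <= radius)
    if (length(inr) == 0) { fn <- fn + 1L; next }
    tp[inr[which.min(dd[inr])]] <- TRUE
  }
  list(n_tp = sum(tp), n_fp = nd - sum(tp), n_fn = fn)
}

# optimal assignment by exhaustive permutation search (small instances)
oracle_assignment_total <- function(J) {
  na <- nrow(J); nb <- ncol(J)
  if (na <= nb) {
    perms <- .permutations(seq_len(nb))
    best <- 0
    for (p in perms) {
      tot <- sum(J[cbind(seq_len(na), p[seq_len(na)])])
      if (tot > best) best <- tot
    }
  } else {
    return(oracle_assignment_total(t(J)))
  }
  best
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# BFS rows on the touching graph built from scratch
oracle_rows <- function(labels_arr, distal_cell) {
  ids <- sort(setdiff(unique(as.integer(labels_arr)), 0L))
  d <- dim(labels_arr)
  adj <- matrix(FALSE, length(ids), length(ids))
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    a <- labels_arr[x, y, z]
    if (a == 0) next
    for (s in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      xx <- x + s[1]; yy <- y + s[2]; zz <- z + s[3]
      if (xx > d[1] || yy > d[2] || zz > d[3]) next
      b <- labels_arr[xx, yy, zz]
      if (b > 0 && b != a) {
        ia <- match(a, ids); ib <- match(b, ids)
        adj[ia, ib] <- TRUE; adj[ib, ia] <- TRUE
      }
    }
  }
  row <- rep(NA_real_, length(ids))
  start <- match(distal_cell, ids)
  row[start] <- 1
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      nb <- which(adj[f, ] & is.na(row))
      row[nb] <- row[f] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  tibble::tibble(cell = ids, row = row)
}

# brute-force 3x3 symmetric eigen solver via base eigen (per voxel)
oracle_hessian_eigen <- function(arr, spacing) {
  d <- dim(arr)
  sh <- function(ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  sx <- spacing[1]; sy <- spacing[2]; sz <- spacing[3]
  sh2 <- function(a1, b1, a2, b2) {
    idx <- lapply(d, seq_len)
    idx[[a1]] <- pmin(pmax(idx[[a1]] + b1, 1L), d[a1])
    idx[[a2]] <- pmin(pmax(idx[[a2]] + b2, 1L), d[a2])
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  H <- list(xx = (sh(1, 1) - 2 * arr + sh(1, -1)) / sx^2,
            yy = (sh(2, 1) - 2 * arr + sh(2, -1)) / sy^2,
            zz = (sh(3, 1) - 2 * arr + sh(3, -1)) / sz^2,
            xy = (sh2(1, 1, 2, 1) - sh2(1, 1, 2, -1) - sh2(1, -1, 2, 1) + sh2(1, -1, 2, -1)) / (4 * sx * sy),
            xz = (sh2(1, 1, 3, 1) - sh2(1, 1, 3, -1) - sh2(1, -1, 3, 1) + sh2(1, -1, 3, -1)) / (4 * sx * sz),
            yz = (sh2(2, 1, 3, 1) - sh2(2, 1, 3, -1) - sh2(2, -1, 3, 1) + sh2(2, -1, 3, -1)) / (4 * sy * sz))
  d1 <- array(0, d); d2 <- array(0, d); d3 <- array(0, d)
  for (i in seq_along(d1)) {
    m <- matrix(c(H$xx[i], H$xy[i], H$xz[i],
                  H$xy[i], H$yy[i], H$yz[i],
                  H$xz[i], H$yz[i], H$zz[i]), 3, 3)
    ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    d1[i] <- ev[1]; d2[i] <- ev[2]; d3[i] <- ev[3]
  }
  list(d1 = d1, d2 = d2, d3 = d3)
}

# plain-loop 2-D sliding mean (window w x w, mirrored borders) per z-plane
oracle_sliding_mean <- function(plane, w) {
  h <- w %/% 2
  out <- plane
  nr <- nrow(plane); nc <- ncol(plane)
  refl <- function(a, n) {
    if (a < 1) a <- 1 - a
    if (a > n) a <- 2 * n - a + 1
    min(max(a, 1), n)
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in (i - h):(i + h)) for (b in (j - h):(j + h))
      acc <- acc + plane[refl(a, nr), refl(b, nc)]
    out[i, j] <- acc / w^2
  }
  out
}
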