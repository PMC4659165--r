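# Sliding-window cell-centre detector: mean-brightness + HOG features over
# xy and xz windows through the candidate centre, scored by a linear SVM
# (w^T v > tau). Training uses hard-negative mining (equivalent to training
# on all negatives) and latent re-estimation of positive centres; detection
# scans multiple scales and suppresses overlapping detections.

#' Detector configuration
#'
#' @param cell_radius_um one cell radius (suppression radius; negatives are
#'   mined farther than this from every positive).
#' @param window_um detection window side (default 2 x cell diameter).
#' @param grid HOG sub-window grid (grid x grid non-overlapping cells).
#' @param nbins orientation bins (gradients binned into 18 orientations).
#' @param scale_range detector scale factors (applied to window sampling).
#' @param n_scales number of geometric scale steps.
#' @param cost SVM regularisation C.
#' @param max_rounds hard-negative mining round cap.
#' @param latent_passes latent re-centering passes.
#' @param latent_radius_um re-centering search radius (default half cell
#'   radius).
#' @param stride scan stride in voxels (x, y, z).
#' @param n_init_negatives initial random negatives per positive.
#' @param negatives_per_round mined negatives added per round.
#' @return List of class `detector_config`.
#' @export
detector_config <- function(cell_radius_um = 2,
                            window_um = 4 * cell_radius_um,
                            grid = 4L, nbins = 18L,
                            scale_range = c(0.7, 1.5), n_scales = 5L,
                            cost = 1, max_rounds = 5L,
                            latent_passes = 2L,
                            latent_radius_um = cell_radius_um / 2,
                            stride = c(1L, 1L, 1L),
                            n_init_negatives = 3L,
                            negatives_per_round = 200L) {
  structure(list(cell_radius_um = cell_radius_um, window_um = window_um,
                 grid = as.integer(grid), nbins = as.integer(nbins),
                 scale_range = scale_range, n_scales = as.integer(n_scales),
                 cost = cost, max_rounds = as.integer(max_rounds),
                 latent_passes = as.integer(latent_passes),
                 latent_radius_um = latent_radius_um,
                 stride = rep_len(as.integer(stride), 3L),
                 n_init_negatives = as.integer(n_init_negatives),
                 negatives_per_round = as.integer(negatives_per_round)),
            class = "detector_config")
}

# window size in voxels (even, divisible by grid) for a stack
.win_vox <- function(config, spacing) {
  w <- round(config$window_um / spacing[1])
  w <- max(config$grid * 2L, as.integer(ceiling(w / config$grid) * config$grid))
  w
}

#' Extract detection-window features at a centre
#'
#' Features: mean brightness of the xy window, then an 18-orientation HOG
#' block for the xy window and one for the xz window. Each block is a
#' `grid x grid` layout of non-overlapping sub-windows; per sub-window the
#' magnitude-weighted orientation histogram is L2-normalised and the
#' normalisation factor is appended as an extra feature. Windows outside
#' the stack are zero-padded.
#'
#' @param stack a `voxel_stack`.
#' @param center_um centre in micrometres (length 3).
#' @param scale window sampling scale factor.
#' @param config a [detector_config()].
#' @param flip_u,flip_v mirror the window (used for training-time
#'   symmetrisation).
#' @return Numeric feature vector.
#' @export
extract_window_features <- function(stack, center_um, scale = 1,
                                    config = detector_config(),
                                    flip_u = FALSE, flip_v = FALSE) {
  v <- .um_to_vox_clamped(rbind(center_um), stack$spacing, dim(stack$data))[1, ]
  win <- .win_vox(config, stack$spacing)
  cpp_window_features(as.numeric(stack$data), dim(stack$data), v, win,
                      config$grid, config$nbins, scale, flip_u, flip_v)
}

# linear-SVM weight vector from an e1071 model
.svm_w <- function(model) {
  w <- crossprod(model$coefs, model$SV)
  as.numeric(w)
}

# train linear SVM on explicit feature matrices; returns w and rho oriented
# so that positives (y = 1) score high
.svm_fit <- function(X, y, cost) {
  m <- e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
                  cost = cost, scale = FALSE)
  w <- .svm_w(m)
  rho <- m$rho
  sc <- as.numeric(X %*% w) - rho
  if (stats::cor(sc, y) < 0) { w <- -w; rho <- -rho }
  list(w = w, rho = rho)
}

# hard-negative mining over an explicit candidate pool: train on a subset of
# negatives, add violators (score > -1, within the margin), retrain until no
# new violators or the round cap. Mathematically equivalent to training on
# the full pool (same support vectors).
svm_mine <- function(X_pos, X_negpool, cost, init = min(16L, nrow(X_negpool)),
                     max_rounds = 20L, chunk = 256L) {
  act <- seq_len(init)
  fit <- NULL
  for (round in seq_len(max_rounds)) {
    X <- rbind(X_pos, X_negpool[act, , drop = FALSE])
    y <- c(rep(1, nrow(X_pos)), rep(-1, length(act)))
    fit <- .svm_fit(X, y, cost)
    sc <- as.numeric(X_negpool %*% fit$w) - fit$rho
    viol <- setdiff(which(sc > -1 + 1e-8), act)
    if (length(viol) == 0) break
    viol <- viol[order(sc[viol], decreasing = TRUE)]
    act <- c(act, head(viol, chunk))
  }
  c(fit, list(rounds = round, n_active = length(act)))
}

#' Train the sliding-window cell detector
#'
#' Positives are the annotated centres (augmented with left-right and
#' top-bottom mirrored windows); negatives are mined from windows farther
#' than one cell radius from every positive, iteratively adding the
#' highest-scoring false positives until none scores inside the margin
#' (equivalent to training on all negatives). One or more latent passes
#' re-estimate each positive centre as the response maximum within half a
#' cell radius and retrain.
#'
#' @param stacks list of `voxel_stack`s (or a single stack).
#' @param positive_centers list of micrometre centre matrices (one per
#'   stack).
#' @param config a [detector_config()].
#' @param seed RNG seed for negative sampling.
#' @return A `vox_detector` model (weights, threshold origin, geometry,
#'   training log).
#' @export
train_detector <- function(stacks, positive_centers, config = detector_config(),
                           seed = 1L) {
  if (inherits(stacks, "voxel_stack")) stacks <- list(stacks)
  if (is.matrix(positive_centers)) positive_centers <- list(positive_centers)
  stopifnot(length(stacks) == length(positive_centers))
  n_pos_total <- sum(vapply(positive_centers, nrow, integer(1)))
  if (n_pos_total < 10) stop("need at least 10 positive examples")
  set.seed(sub_seed(seed, 3L))

  pos_feats <- function(centers) {
    do.call(rbind, lapply(seq_along(stacks), function(si) {
      cen <- centers[[si]]
      if (nrow(cen) == 0) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(cen)), function(i) {
        rbind(extract_window_features(stacks[[si]], cen[i, ], 1, config),
              extract_window_features(stacks[[si]], cen[i, ], 1, config, TRUE, FALSE),
              extract_window_features(stacks[[si]], cen[i, ], 1, config, FALSE, TRUE),
              extract_window_features(stacks[[si]], cen[i, ], 1, config, TRUE, TRUE))
      }))
    }))
  }

  sample_negatives <- function(n_per_stack) {
    do.call(rbind, lapply(seq_along(stacks), function(si) {
      st <- stacks[[si]]
      d <- dim(st$data)
      cen <- positive_centers[[si]]
      feats <- list()
      tries <- 0L
      while (length(feats) < n_per_stack && tries < 50L * n_per_stack) {
        tries <- tries + 1L
        p <- runif(3) * (d - 1) * st$spacing
        if (nrow(cen) > 0 &&
            min(sqrt(colSums((t(cen) - p)^2))) <= config$cell_radius_um) next
        feats[[length(feats) + 1L]] <- extract_window_features(st, p, 1, config)
      }
      do.call(rbind, feats)
    }))
  }

  centers <- positive_centers
  Xp <- pos_feats(centers)
  Xn <- sample_negatives(config$n_init_negatives * max(1L, ceiling(n_pos_total / length(stacks))))
  if (is.null(Xn) || nrow(Xn) == 0) stop("no negatives available")
  log_lines <- character()

  fit_current <- function(Xp, Xn) {
    X <- rbind(Xp, Xn)
    y <- c(rep(1, nrow(Xp)), rep(-1, nrow(Xn)))
    .svm_fit(X, y, config$cost)
  }
  fit <- fit_current(Xp, Xn)

  mine_round <- function(fit, Xn) {
    added <- 0L
    for (si in seq_along(stacks)) {
      st <- stacks[[si]]
      d <- dim(st$data)
      win <- .win_vox(config, st$spacing)
      sc <- cpp_scan_scores(as.numeric(st$data), d, fit$w, win, config$grid,
                            config$nbins, 1, config$stride)
      sc <- array(sc, dim = d)
      cen <- positive_centers[[si]]
      cand <- which(sc - fit$rho > -1 + 1e-8, arr.ind = TRUE) - 1L
      if (nrow(cand) == 0) next
      pos_um <- vox_to_um(cand, st$spacing)
      if (nrow(cen) > 0) {
        dmin <- apply(pos_um, 1, function(p) min(sqrt(colSums((t(cen) - p)^2))))
        keep <- dmin > config$cell_radius_um
      } else keep <- rep(TRUE, nrow(pos_um))
      if (!any(keep)) next
      pos_um <- pos_um[keep, , drop = FALSE]
      vals <- sc[cand[keep, , drop = FALSE] + 1L]
      ord <- order(vals, decreasing = TRUE)
      take <- head(ord, config$negatives_per_round)
      nf <- do.call(rbind, lapply(take, function(i)
        extract_window_features(st, pos_um[i, ], 1, config)))
      Xn <- rbind(Xn, nf)
      added <- added + length(take)
    }
    list(added = added, Xn = Xn)
  }

  for (round in seq_len(config$max_rounds)) {
    mr <- mine_round(fit, Xn)
    Xn <- mr$Xn
    log_lines <- c(log_lines, sprintf("mining round %d: +%d negatives (total %d)",
                                      round, mr$added, nrow(Xn)))
    if (mr$added == 0) break
    fit <- fit_current(Xp, Xn)
  }
  if (round == config$max_rounds && mr$added > 0)
    warning("hard-negative mining stopped at round cap")

  # latent re-centering of positives
  for (pass in seq_len(config$latent_passes)) {
    moved <- 0
    for (si in seq_along(stacks)) {
      st <- stacks[[si]]
      d <- dim(st$data)
      win <- .win_vox(config, st$spacing)
      sc <- array(cpp_scan_scores(as.numeric(st$data), d, fit$w, win,
                                  config$grid, config$nbins, 1,
                                  config$stride), dim = d)
      cen <- centers[[si]]
      r_vox <- ceiling(config$latent_radius_um / st$spacing)
      for (i in seq_len(nrow(cen))) {
        v <- .um_to_vox_clamped(cen[i, , drop = FALSE], st$spacing, d)[1, ]
        lo <- pmax(v - r_vox, 0L); hi <- pmin(v + r_vox, d - 1L)
        sub <- sc[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L,
                  drop = FALSE]
        cc <- box_coords(lo, hi)
        pos <- vox_to_um(cc, st$spacing)
        inball <- sqrt(colSums((t(pos) - cen[i, ])^2)) <= config$latent_radius_um
        vals <- as.numeric(sub)
        vals[!inball] <- -Inf
        best <- which.max(vals)
        newc <- pos[best, ]
        if (any(newc != cen[i, ])) moved <- moved + 1
        cen[i, ] <- newc
      }
      centers[[si]] <- cen
    }
    log_lines <- c(log_lines, sprintf("latent pass %d: %d centres moved", pass, moved))
    Xp <- pos_feats(centers)
    fit <- fit_current(Xp, Xn)
  }

  structure(list(w = fit$w, rho = fit$rho, config = config,
                 n_positives = n_pos_total, n_negatives = nrow(Xn),
                 centers = centers, log = log_lines),
            class = "vox_detector")
}

#' @export
print.vox_detector <- function(x, ...) {
  cat(sprintf("<vox_detector: %d features, %d positives, %d mined negatives>\n",
              length(x$w), x$n_positives, x$n_negatives))
  invisible(x)
}

#' Tidy a detector model
#'
#' @param x a `vox_detector`.
#' @param ... unused.
#' @return Tibble of weight components.
#' @export
tidy.vox_detector <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$w), weight = x$w)
}

#' Scan a stack with a trained detector
#'
#' Scores every window (at the configured stride) at each scale in the
#' configured range, keeps responses with `w^T v > tau`, maps coordinates
#' back to micrometres, and (optionally) suppresses detections overlapping a
#' higher-scoring detection within one cell radius.
#'
#' @param stack a `voxel_stack`.
#' @param model a `vox_detector`.
#' @param tau detection threshold applied to `w^T v`.
#' @param suppress apply [nonmax_suppress()] with radius = one cell radius.
#' @param max_detections cap on raw above-threshold windows (the
#'   highest-scoring are kept) so that low thresholds stay tractable.
#' @return A `detection_set` tibble.
#' @export
scan_detect <- function(stack, model, tau, suppress = TRUE,
                        max_detections = 5000L) {
  config <- model$config
  d <- dim(stack$data)
  win <- .win_vox(config, stack$spacing)
  scales <- exp(seq(log(config$scale_range[1]), log(config$scale_range[2]),
                    length.out = config$n_scales))
  all <- list()
  for (s in scales) {
    sc <- array(cpp_scan_scores(as.numeric(stack$data), d, model$w, win,
                                config$grid, config$nbins, s, config$stride),
                dim = d)
    hit <- which(sc > tau, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    um <- vox_to_um(hit - 1L, stack$spacing)
    all[[length(all) + 1L]] <- tibble::tibble(
      x_um = um[, 1], y_um = um[, 2], z_um = um[, 3],
      score = sc[hit], scale = s)
  }
  if (length(all) == 0)
    return(detection_set(numeric(0), numeric(0), numeric(0)))
  df <- do.call(rbind, all)
  if (nrow(df) > max_detections)
    df <- df[order(df$score, decreasing = TRUE)[seq_len(max_detections)], ]
  dets <- detection_set(df$x_um, df$y_um, df$z_um, df$score, df$scale)
  if (suppress) dets <- nonmax_suppress(dets, config$cell_radius_um)
  dets
}

#' Greedy non-maximum suppression
#'
#' Detections are processed by descending score (ties broken by insertion
#' order); a detection is removed iff a kept higher-scoring detection lies
#' within `radius_um`.
#'
#' @param dets detection table.
#' @param radius_um suppression radius (micrometres).
#' @return Suppressed `detection_set`.
#' @export
nonmax_suppress <- function(dets, radius_um) {
  stopifnot(radius_um > 0)
  if (nrow(dets) <= 1) return(dets)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  pts <- as.matrix(dets[, c("x_um", "y_um", "z_um")])
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        min(sqrt(colSums((t(pts[kept, , drop = FALSE]) - pts[i, ])^2))) > radius_um)
      kept <- c(kept, i)
  }
  out <- dets[sort(kept), ]
  out$id <- seq_len(nrow(out))
  out
}
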