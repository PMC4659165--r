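# Benchmarking metrics: detection matching at a 1.5 um radius, average
# precision over all thresholds, Jaccard overlap and average overlap (AO)
# under an optimal one-to-one matching between predicted and reference
# segments.

#' Match detections against annotated centres
#'
#' A detection is a true positive iff it lies within `radius_um` of an
#' annotated centre and no other detection is closer to that centre (i.e. it
#' is the nearest-in-radius detection of some centre). All other detections
#' are false positives. An annotated centre with no detection within
#' `radius_um` is a false negative.
#'
#' @param dets detection table (micrometre coordinates).
#' @param truth_centers matrix (n x 3) of annotated centres (micrometres).
#' @param radius_um matching radius (1.5 um, approximately one cell radius).
#' @return List: logical `tp` per detection, counts, `precision`, `recall`.
#' @export
match_detections <- function(dets, truth_centers, radius_um = 1.5) {
  pts <- if (is.matrix(dets)) dets else as.matrix(dets[, c("x_um", "y_um", "z_um")])
  truth_centers <- rbind(truth_centers)
  nd <- nrow(pts); nt <- nrow(truth_centers)
  tp <- rep(FALSE, nd)
  matched_truth <- rep(FALSE, nt)
  if (nd > 0 && nt > 0) {
    dm <- matrix(0, nt, nd)
    for (j in 1:3)
      dm <- dm + outer(truth_centers[, j], pts[, j], `-`)^2
    dm <- sqrt(dm)
    for (t in seq_len(nt)) {
      inr <- which(dm[t, ] <= radius_um)
      if (length(inr) == 0) next
      matched_truth[t] <- TRUE
      tp[inr[which.min(dm[t, inr])]] <- TRUE
    }
  }
  ntp <- sum(tp); nfp <- nd - ntp; nfn <- sum(!matched_truth)
  list(tp = tp, n_tp = ntp, n_fp = nfp, n_fn = nfn,
       precision = if (nd > 0) ntp / nd else NA_real_,
       recall = if (nt > 0) sum(matched_truth) / nt else NA_real_)
}

#' Average precision over all detection thresholds
#'
#' Sweeps the threshold over all distinct scores (descending), recomputes
#' precision and recall at each operating point via [match_detections()],
#' and sums precision over recall increments (un-interpolated area under the
#' precision-recall curve). Score ties are handled by including all tied
#' detections at once.
#'
#' @param dets scored detection table.
#' @param truth_centers annotated centres (micrometres).
#' @param radius_um matching radius.
#' @return List: `ap` scalar, and the precision/recall sweep as a tibble.
#' @export
average_precision <- function(dets, truth_centers, radius_um = 1.5) {
  truth_centers <- rbind(truth_centers)
  if (nrow(truth_centers) == 0) stop("average precision undefined for empty truth")
  if (nrow(dets) == 0)
    return(list(ap = 0, curve = tibble::tibble(tau = numeric(0),
                                               precision = numeric(0),
                                               recall = numeric(0))))
  stopifnot(all(is.finite(dets$score)))
  taus <- sort(unique(dets$score), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  rows <- vector("list", length(taus))
  for (i in seq_along(taus)) {
    sub <- dets[dets$score >= taus[i], , drop = FALSE]
    mr <- match_detections(sub, truth_centers, radius_um)
    ap <- ap + (mr$recall - prev_rec) * mr$precision
    prev_rec <- mr$recall
    rows[[i]] <- tibble::tibble(tau = taus[i], precision = mr$precision,
                                recall = mr$recall)
  }
  list(ap = ap, curve = do.call(rbind, rows))
}

#' Jaccard index of two masks
#'
#' Intersection volume over union volume. Two empty masks give 0 with a
#' warning.
#'
#' @param a,b logical arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both masks empty; Jaccard defined as 0")
    return(0)
  }
  sum(a & b) / uni
}

#' Segmentation average overlap under optimal matching
#'
#' Computes the pairwise Jaccard matrix between segments of `pred` and
#' `ref`, finds the one-to-one assignment maximising total Jaccard
#' (maximum-weight bipartite matching), and reports AO = mean Jaccard over
#' matched pairs, plus segment-level precision and recall (a matched pair
#' with Jaccard >= `match_threshold` counts as a segment-level true
#' positive).
#'
#' @param pred,ref `label_volume`s (or integer arrays) of identical shape.
#' @param match_threshold Jaccard cut for segment-level precision/recall.
#' @return List: `ao`, `precision`, `recall`, `matches` tibble, and the
#'   Jaccard matrix.
#' @export
segmentation_ao <- function(pred, ref, match_threshold = 0.5) {
  A <- if (inherits(pred, "label_volume")) pred$labels else pred
  B <- if (inherits(ref, "label_volume")) ref$labels else ref
  if (!identical(dim(A), dim(B))) stop("label volume shape mismatch")
  ids_a <- sort(setdiff(unique(as.integer(A)), 0L))
  ids_b <- sort(setdiff(unique(as.integer(B)), 0L))
  na <- length(ids_a); nb <- length(ids_b)
  if (na == 0 || nb == 0)
    return(list(ao = 0, precision = 0, recall = 0,
                matches = tibble::tibble(pred = integer(0), ref = integer(0),
                                         jaccard = numeric(0)),
                jaccard_matrix = matrix(0, na, nb)))
  nz <- A > 0L | B > 0L
  av <- as.integer(A)[nz]; bv <- as.integer(B)[nz]
  keep <- av > 0L & bv > 0L
  J <- matrix(0, na, nb, dimnames = list(ids_a, ids_b))
  size_a <- setNames(tabulate(factor(av[av > 0L], levels = ids_a)), ids_a)
  size_b <- setNames(tabulate(factor(bv[bv > 0L], levels = ids_b)), ids_b)
  if (any(keep)) {
    inter <- table(factor(av[keep], levels = ids_a), factor(bv[keep], levels = ids_b))
    inter <- unclass(inter)
    uni <- outer(size_a, size_b, `+`) - inter
    J <- inter / uni
  }
  # maximum-weight one-to-one assignment on pairs with positive overlap
  pairs <- which(J > 0, arr.ind = TRUE)
  matches <- tibble::tibble(pred = integer(0), ref = integer(0), jaccard = numeric(0))
  if (nrow(pairs) > 0) {
    edges <- as.vector(t(cbind(pairs[, 1], na + pairs[, 2])))
    g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)), edges)
    mm <- igraph::max_bipartite_match(g, weights = J[pairs])
    mt <- mm$matching[seq_len(na)]
    sel <- !is.na(mt)
    pi <- which(sel); ri <- mt[sel] - na
    jj <- J[cbind(pi, ri)]
    pos <- jj > 0
    matches <- tibble::tibble(pred = ids_a[pi[pos]], ref = ids_b[ri[pos]],
                              jaccard = jj[pos])
  }
  ao <- if (nrow(matches) > 0) mean(matches$jaccard) else 0
  n_good <- sum(matches$jaccard >= match_threshold)
  list(ao = ao, precision = n_good / na, recall = n_good / nb,
       matches = matches, jaccard_matrix = J)
}
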