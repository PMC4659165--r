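# Shared containers and readers/writers.
#
# Conventions used throughout the package:
#  * voxel indices are 0-based and addressed (x, y, z) with half-open ranges;
#  * physical coordinates in micrometres are index * spacing (voxel-centre
#    convention);
#  * a label volume is an integer array where 0 is background and value k is
#    the mask of cell k, so masks are pairwise disjoint by construction.

#' Construct a voxel stack
#'
#' A voxel stack is a 3-D scalar intensity grid together with its anisotropic
#' voxel spacing in micrometres and an optional channel name.
#'
#' @param data 3-D numeric array, indexed (x, y, z).
#' @param spacing numeric length-3, micrometres per voxel along (x, y, z).
#' @param channel optional channel name.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(data, spacing, channel = "unnamed") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 1L))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (any(!is.finite(data)) || any(data < 0))
    stop("stack intensities must be finite and non-negative")
  structure(list(data = data, spacing = spacing, channel = as.character(channel)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat(sprintf("<voxel_stack '%s' %s voxels, spacing %s um, range [%.4g, %.4g]>\n",
              x$channel, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$data)

#' Construct a label volume
#'
#' @param labels integer 3-D array; 0 = background, value k = mask of cell k.
#' @param spacing voxel spacing in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  stopifnot(length(dim(labels)) == 3L, all(labels >= 0L))
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s voxels, %d cells>\n",
              paste(dim(x$labels), collapse = "x"),
              length(setdiff(unique(as.integer(x$labels)), 0L))))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Convert voxel indices to physical coordinates and back
#'
#' @param idx matrix (n x 3) of 0-based voxel indices.
#' @param spacing voxel spacing (micrometres).
#' @return Matrix of physical coordinates in micrometres (or voxel indices).
#' @export
vox_to_um <- function(idx, spacing) {
  idx <- rbind(idx)
  sweep(idx, 2, as.numeric(spacing), `*`)
}

#' @rdname vox_to_um
#' @param um matrix (n x 3) of micrometre coordinates.
#' @export
um_to_vox <- function(um, spacing) {
  um <- rbind(um)
  round(sweep(um, 2, as.numeric(spacing), `/`))
}

# internal: nearest in-bounds voxel of a micrometre coordinate matrix
.um_to_vox_clamped <- function(um, spacing, dims) {
  v <- um_to_vox(um, spacing)
  for (j in 1:3) v[, j] <- pmin(pmax(v[, j], 0L), dims[j] - 1L)
  storage.mode(v) <- "integer"
  v
}

#' Read a (multi-page) TIFF into one or more voxel stacks
#'
#' Multi-page TIFFs are read as z-planes. Multi-sample (multi-channel) TIFFs
#' are split into one stack per channel.
#'
#' @param path TIFF file.
#' @param spacing voxel spacing (micrometres per voxel along x, y, z).
#' @param channels optional channel names.
#' @return A `voxel_stack`, or a named list of them for multi-channel files.
#' @export
load_stack <- function(path, spacing, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in ", path)
  nchan <- if (length(shp) == 3L) shp[3] else 1L
  one <- function(ch) {
    planes <- lapply(pages, function(p) {
      m <- if (length(dim(p)) == 3L) p[, , ch] else p
      # readTIFF returns row-major matrices (row = y); transpose to (x, y)
      t(m)
    })
    arr <- array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
    voxel_stack(arr, spacing,
                channel = if (!is.null(channels)) channels[ch] else paste0("ch", ch))
  }
  if (nchan == 1L) one(1L) else {
    out <- lapply(seq_len(nchan), one)
    names(out) <- vapply(out, function(s) s$channel, character(1))
    out
  }
}

#' Write a voxel stack to a multi-page 32-bit float TIFF
#'
#' @param stack a `voxel_stack`.
#' @param path output file.
#' @export
save_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(z) t(stack$data[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read / write label volumes as 16-bit TIFF (pixel value = cell index)
#'
#' @param labels a `label_volume`.
#' @param path TIFF file.
#' @return `load_labels` returns a `label_volume`.
#' @export
save_labels <- function(labels, path) {
  mx <- max(labels$labels)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  pages <- lapply(seq_len(dim(labels$labels)[3]),
                  function(z) t(labels$labels[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname save_labels
#' @param spacing voxel spacing of the stored volume.
#' @export
load_labels <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- lapply(pages, t)
  arr <- array(round(unlist(planes) * 65535), dim = c(dim(planes[[1]]), length(planes)))
  label_volume(arr, spacing)
}

#' Build a detection table
#'
#' Detections are tabular: one row per candidate cell centre with micrometre
#' coordinates, a detector score, an optional scale factor, and free-text
#' labels (semicolon-separated, e.g. `"M-phase;half cell"`).
#'
#' @param x,y,z centre coordinates in micrometres.
#' @param score detector score.
#' @param scale detection scale factor (NA if not applicable).
#' @param labels character vector of semicolon-separated annotation labels.
#' @return A tibble with class `detection_set`.
#' @export
detection_set <- function(x, y, z, score = NA_real_, scale = NA_real_,
                          labels = "") {
  out <- tibble::tibble(id = seq_along(x), x_um = as.numeric(x),
                        y_um = as.numeric(y), z_um = as.numeric(z),
                        score = as.numeric(rep_len(score, length(x))),
                        scale = as.numeric(rep_len(scale, length(x))),
                        labels = as.character(rep_len(labels, length(x))))
  if (any(!is.finite(out$score) & !is.na(out$score)))
    stop("detection scores must be finite or NA")
  class(out) <- c("detection_set", class(out))
  out
}

#' @export
as.matrix.detection_set <- function(x, ...) {
  m <- cbind(x$x_um, x$y_um, x$z_um)
  colnames(m) <- c("x_um", "y_um", "z_um")
  m
}

#' Save / load detection tables as CSV (or JSON)
#'
#' Coordinates are written with full double precision; labels roundtrip
#' exactly. Rows with coordinates outside `bounds` trigger a warning on load,
#' not an error.
#'
#' @param dets a detection table (`detection_set` or plain data frame with
#'   columns `x_um`, `y_um`, `z_um`).
#' @param path output file; extension `.json` selects JSON, otherwise CSV.
#' @export
save_detections <- function(dets, path) {
  df <- as.data.frame(dets)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = FALSE)
  } else {
    write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @rdname save_detections
#' @param bounds optional 3-vector of upper micrometre bounds for a
#'   plausibility warning.
#' @export
load_detections <- function(path, bounds = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE, colClasses = c(labels = "character"))
  }
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(df))) stop("malformed detection table: ", path)
  for (cc in c(need, "score", "scale"))
    if (cc %in% names(df)) df[[cc]] <- as.numeric(df[[cc]])
  if (!"labels" %in% names(df)) df$labels <- ""
  df$labels[is.na(df$labels)] <- ""
  if (!is.null(bounds)) {
    out_of_bounds <- df$x_um < 0 | df$y_um < 0 | df$z_um < 0 |
      df$x_um > bounds[1] | df$y_um > bounds[2] | df$z_um > bounds[3]
    if (any(out_of_bounds))
      warning(sum(out_of_bounds), " detections outside declared bounds")
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("detection_set", class(out))
  out
}
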